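#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.delim write.table
NULL

cohort_required_fields <- c("patient_id", "birth_date", "diagnosis_date",
                            "admission_date", "sex", "note_text")
cohort_optional_fields <- c("religion", "stage", "icd10", "icdo_morphology",
                            "cancer_confirmed")
cohort_fields <- c(cohort_required_fields[1:4], "sex", "religion", "stage",
                   "icd10", "icdo_morphology", "note_text", "cancer_confirmed")

#' Exclusion reasons recognized by the cohort filter
#'
#' `ADMISSION_BEFORE_DIAGNOSIS` (admission strictly earlier than the cancer
#' diagnosis), `NOTE_TOO_SHORT` (note below the minimum word count),
#' `NON_MALIGNANT_BEHAVIOR` (ICD-O behavior digit 0 benign or 1 uncertain)
#' and `MISSING_DATE`, the parse flag for records whose admission or
#' diagnosis date is absent (such records are excluded, never silently
#' kept).
#' @export
exclusion_reasons <- c("ADMISSION_BEFORE_DIAGNOSIS", "NOTE_TOO_SHORT",
                       "NON_MALIGNANT_BEHAVIOR", "MISSING_DATE")

parse_cohort_date <- function(x, field, fallback = NULL) {
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  present <- !is.na(x) & nzchar(trimws(x))
  if (!any(present)) return(out)
  d <- as.Date(x[present], format = "%Y-%m-%d")
  if (!is.null(fallback) && any(is.na(d))) {
    d2 <- as.Date(x[present][is.na(d)], format = fallback)
    d[is.na(d)] <- d2
  }
  if (any(is.na(d))) {
    stop("unparseable ", field, " value(s): ",
         paste(sQuote(utils::head(x[present][is.na(d)], 3)), collapse = ", "))
  }
  out[present] <- d
  out
}

as_cohort <- function(df, date_fallback = NULL) {
  missing_cols <- setdiff(cohort_required_fields, names(df))
  if (length(missing_cols)) {
    stop("cohort lacks required field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (f in cohort_optional_fields) if (is.null(df[[f]])) df[[f]] <- NA
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    birth_date = parse_cohort_date(df$birth_date, "birth_date", date_fallback),
    diagnosis_date = parse_cohort_date(df$diagnosis_date, "diagnosis_date",
                                       date_fallback),
    admission_date = parse_cohort_date(df$admission_date, "admission_date",
                                       date_fallback),
    sex = as.character(df$sex),
    religion = as.character(df$religion),
    stage = as.character(df$stage),
    icd10 = as.character(df$icd10),
    icdo_morphology = as.character(df$icdo_morphology),
    note_text = as.character(df$note_text),
    cancer_confirmed = as.logical(df$cancer_confirmed),
    stringsAsFactors = FALSE)
  out$cancer_confirmed[is.na(out$cancer_confirmed)] <- TRUE
  if (anyNA(out$patient_id) || any(!nzchar(out$patient_id))) {
    stop("missing patient_id")
  }
  dup <- duplicated(out$patient_id)
  if (any(dup)) {
    stop("duplicate patient_id: ", sQuote(out$patient_id[which(dup)[1L]]))
  }
  bad_sex <- !is.na(out$sex) & !out$sex %in% c("female", "male")
  if (any(bad_sex)) {
    stop("sex must be 'female' or 'male'; got ",
         sQuote(out$sex[which(bad_sex)[1L]]))
  }
  bd <- behavior_digit(out$icdo_morphology)
  bad_bd <- !is.na(bd) & !bd %in% c(0L, 1L, 2L, 3L, 6L, 9L)
  if (any(bad_bd)) {
    stop("ICD-O behavior digit out of {0,1,2,3,6,9}: ",
         sQuote(out$icdo_morphology[which(bad_bd)[1L]]))
  }
  out
}

#' Parse the ICD-O behavior digit
#'
#' Extracts the digit after `/` in an ICD-O morphology code
#' (e.g. `"8140/3"` has behavior 3, malignant). Returns `NA` where the code
#' is missing or carries no behavior digit.
#'
#' @param morphology character vector of ICD-O morphology codes.
#' @return integer vector of behavior digits.
#' @export
behavior_digit <- function(morphology) {
  out <- rep(NA_integer_, length(morphology))
  has <- !is.na(morphology) & grepl("/\\d", morphology)
  out[has] <- as.integer(sub(".*?/(\\d).*", "\\1", morphology[has]))
  out
}

#' Read a patient cohort from JSONL or CSV
#'
#' One patient per JSONL line (field names as in the cohort schema: see
#' Details) or one per CSV row with identical headers. Dates are ISO-8601
#' (`YYYY-MM-DD`); one fallback `format` pattern may be supplied for
#' legacy files. In JSONL, `icd10` may be an array of code strings; it is
#' stored semicolon-joined.
#'
#' @details Required fields: `patient_id`, `birth_date`, `diagnosis_date`,
#'   `admission_date`, `sex`, `note_text`. Optional: `religion`, `stage`,
#'   `icd10`, `icdo_morphology`, `cancer_confirmed` (defaults to `TRUE`,
#'   the cancer-registry confirmation flag). A present-but-unparseable
#'   required date raises; an absent admission/diagnosis date becomes `NA`
#'   and is handled by [filter_cohort()] with reason `MISSING_DATE`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @param date_fallback optional additional [base::strptime()] date format
#'   tried after ISO-8601.
#' @return data.frame, one row per patient, class `spict_cohort`.
#' @export
read_cohort <- function(path, format = c("auto", "jsonl", "csv"),
                        date_fallback = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    declared <- unique(unlist(lapply(recs, names)))
    missing_cols <- setdiff(cohort_required_fields, declared)
    if (length(missing_cols)) {
      stop("cohort lacks required field(s): ",
           paste(missing_cols, collapse = ", "))
    }
    get <- function(r, f) {
      v <- r[[f]]
      if (is.null(v) || !length(v)) return(NA)
      if (f == "icd10") return(paste(as.character(v), collapse = ";"))
      v[[1]]
    }
    df <- as.data.frame(
      lapply(setNames(nm = cohort_fields), function(f) {
        vapply(recs, function(r) {
          v <- get(r, f)
          if (length(v) == 1L && is.na(v)) NA_character_ else as.character(v)[1]
        }, character(1))
      }),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  out <- as_cohort(df, date_fallback = date_fallback)
  class(out) <- c("spict_cohort", class(out))
  out
}

#' Write a patient cohort to JSONL or CSV
#'
#' Inverse of [read_cohort()]: round-tripping a conforming file reproduces
#' all field values. In JSONL the `icd10` field is written as an array of
#' code strings.
#'
#' @param cohort data.frame as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @inheritParams read_cohort
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  df <- as.data.frame(cohort, stringsAsFactors = FALSE)[, cohort_fields]
  for (f in c("birth_date", "diagnosis_date", "admission_date")) {
    df[[f]] <- format(df[[f]], "%Y-%m-%d")
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    rec <- as.list(df[i, , drop = FALSE])
    rec <- rec[!vapply(rec, function(v) is.na(v), logical(1))]
    if (!is.null(rec$icd10)) {
      rec$icd10 <- strsplit(rec$icd10, ";", fixed = TRUE)[[1]]
    }
    if (!is.null(rec$cancer_confirmed)) {
      rec$cancer_confirmed <- as.logical(rec$cancer_confirmed)
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Apply the cohort inclusion/exclusion filters
#'
#' Excludes records whose admission date strictly precedes the cancer
#' diagnosis date, whose note holds fewer than `min_words` words (counted
#' with [count_words()] so the rule is language-aware), or whose ICD-O
#' behavior digit is 0 (benign) or 1 (uncertain behavior). Records with a
#' missing admission or diagnosis date are excluded with the parse flag
#' `MISSING_DATE`. Equal admission and diagnosis dates are included. A
#' record may carry several reasons; it is counted once as excluded.
#'
#' @param cohort data.frame of patient records.
#' @param min_words minimum note length in words; records with
#'   `count_words < min_words` are excluded (default 1000).
#' @param lex [lexicon()] used for word counting.
#' @return list with `included` (the retained records) and `report`
#'   (a `cohort_filter_report`: `n_input`, `n_included`, per-reason
#'   `counts`, and long-form `exclusions` data.frame of
#'   `(patient_id, reason)`).
#' @export
filter_cohort <- function(cohort, min_words = 1000,
                          lex = default_lexicon()) {
  n <- nrow(cohort)
  wc <- vapply(cohort$note_text, count_words, integer(1), lex = lex,
               USE.NAMES = FALSE)
  bd <- behavior_digit(cohort$icdo_morphology)
  missing_date <- is.na(cohort$admission_date) | is.na(cohort$diagnosis_date)
  reason_mat <- cbind(
    ADMISSION_BEFORE_DIAGNOSIS = !missing_date &
      cohort$admission_date < cohort$diagnosis_date,
    NOTE_TOO_SHORT = wc < min_words,
    NON_MALIGNANT_BEHAVIOR = !is.na(bd) & bd %in% c(0L, 1L),
    MISSING_DATE = missing_date)
  excluded <- rowSums(reason_mat) > 0
  long <- which(reason_mat, arr.ind = TRUE)
  exclusions <- data.frame(
    patient_id = cohort$patient_id[long[, "row"]],
    reason = colnames(reason_mat)[long[, "col"]],
    stringsAsFactors = FALSE)
  exclusions <- exclusions[order(match(exclusions$patient_id,
                                       cohort$patient_id)), , drop = FALSE]
  rownames(exclusions) <- NULL
  report <- structure(
    list(n_input = n,
         n_included = sum(!excluded),
         counts = setNames(as.integer(colSums(reason_mat)),
                           colnames(reason_mat)),
         exclusions = exclusions,
         min_words = min_words),
    class = "cohort_filter_report")
  included <- cohort[!excluded, , drop = FALSE]
  rownames(included) <- NULL
  list(included = included, report = report)
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat("Cohort filter report\n")
  cat("  input records:   ", x$n_input, "\n")
  cat("  included:        ", x$n_included, "\n")
  cat("  excluded:        ", x$n_input - x$n_included, "\n")
  for (r in names(x$counts)) {
    cat(sprintf("    %-27s %d\n", r, x$counts[[r]]))
  }
  invisible(x)
}

#' Write a filter report
#'
#' Writes the long-form exclusion table as CSV and, alongside it, a JSON
#' summary (`n_input`, `n_included`, per-reason counts).
#'
#' @param report a `cohort_filter_report` from [filter_cohort()].
#' @param csv_path path for the `(patient_id, reason)` CSV.
#' @param json_path path for the JSON summary; default replaces the CSV
#'   extension.
#' @return `csv_path`, invisibly.
#' @export
write_filter_report <- function(report, csv_path,
                                json_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(report$exclusions, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(n_input = report$n_input, n_included = report$n_included,
         counts = as.list(report$counts), min_words = report$min_words),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
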