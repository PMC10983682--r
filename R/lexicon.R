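#' Construct a term lexicon
#'
#' A lexicon maps surface patterns (words, phrases or regular expressions) to
#' one of the six SPICT-LIS general indicators and to the nested keyword
#' profiles (`strict` and/or `relaxed`), and additionally carries negation
#' cues and scope-breaker strings used by [assign_polarity()].
#'
#' The strict keyword set is required to be nested inside the relaxed set:
#' every entry tagged `strict` must also be tagged `relaxed`. This mirrors
#' the design of the two screening profiles, where the relaxed profile adds
#' broader synonyms on top of the explicit strict terms.
#'
#' @param entries data.frame with columns `surface` (character, non-empty),
#'   `match_kind` (`"literal"` or `"regex"`), `script` (`"segmented"`,
#'   `"unsegmented"` or `"either"`), `indicator_id` (integer 1..6),
#'   `strict`, `relaxed` (logical) and optionally `comment`.
#' @param cues data.frame with columns `surface`, `direction` (`"pre"` or
#'   `"post"`) and `window` (positive integer, tokens).
#' @param scope_breakers character vector of strings that cut negation scope
#'   (typically sentence/clausal terminators such as `"."`, `";"`, `"but"`).
#' @return An object of class `spict_lexicon`.
#' @seealso [load_lexicon()], [default_lexicon()], [profile_view()]
#' @export
lexicon <- function(entries, cues = NULL, scope_breakers = character()) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (is.null(entries$comment)) entries$comment <- ""
  needed <- c("surface", "match_kind", "script", "indicator_id",
              "strict", "relaxed")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols)) {
    stop("lexicon entries lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  entries$surface <- as.character(entries$surface)
  entries$indicator_id <- as.integer(entries$indicator_id)
  entries$strict <- as.logical(entries$strict)
  entries$relaxed <- as.logical(entries$relaxed)
  if (is.null(cues)) {
    cues <- data.frame(surface = character(), direction = character(),
                       window = integer(), stringsAsFactors = FALSE)
  }
  cues <- as.data.frame(cues, stringsAsFactors = FALSE)
  cues$window <- as.integer(cues$window)
  obj <- structure(
    list(entries = entries[, c(needed, "comment")],
         cues = cues,
         scope_breakers = as.character(scope_breakers)),
    class = "spict_lexicon")
  validate_lexicon(obj)
  obj
}

validate_lexicon <- function(x) {
  e <- x$entries
  if (any(!nzchar(e$surface))) stop("lexicon contains an empty surface")
  bad_kind <- !e$match_kind %in% c("literal", "regex")
  if (any(bad_kind)) {
    stop("invalid match_kind for surface(s): ",
         paste(sQuote(e$surface[bad_kind]), collapse = ", "))
  }
  bad_script <- !e$script %in% c("segmented", "unsegmented", "either")
  if (any(bad_script)) {
    stop("invalid script for surface(s): ",
         paste(sQuote(e$surface[bad_script]), collapse = ", "))
  }
  if (any(is.na(e$indicator_id)) || any(!e$indicator_id %in% 1:6)) {
    stop("indicator_id must be an integer in 1..6")
  }
  # nesting invariant: strict terms are a subset of relaxed terms
  viol <- which(e$strict & !e$relaxed)
  if (length(viol)) {
    stop("strict-only entry violates profile nesting (strict implies relaxed): ",
         "row ", viol[1L], ", surface ", sQuote(e$surface[viol[1L]]))
  }
  if (any(!e$strict & !e$relaxed)) {
    stop("entry belongs to no profile: surface ",
         sQuote(e$surface[which(!e$strict & !e$relaxed)[1L]]))
  }
  dup <- duplicated(e[, c("surface", "indicator_id")])
  if (any(dup)) {
    stop("duplicate (surface, indicator_id) pair: ",
         sQuote(e$surface[which(dup)[1L]]))
  }
  for (i in which(e$match_kind == "regex")) {
    ok <- tryCatch({ grepl(e$surface[i], "", perl = TRUE); TRUE },
                   error = function(err) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop("regex does not compile: ", sQuote(e$surface[i]))
  }
  cu <- x$cues
  if (nrow(cu)) {
    if (any(!nzchar(cu$surface))) stop("negation cue with empty surface")
    if (any(!cu$direction %in% c("pre", "post"))) {
      stop("cue direction must be 'pre' or 'post'")
    }
    if (any(is.na(cu$window)) || any(cu$window < 1L)) {
      stop("cue window must be a positive integer")
    }
  }
  invisible(x)
}

#' @export
print.spict_lexicon <- function(x, ...) {
  e <- x$entries
  cat("SPICT-LIS term lexicon\n")
  cat("  entries: ", nrow(e),
      " (strict ", sum(e$strict), ", relaxed ", sum(e$relaxed), ")\n", sep = "")
  tab <- table(factor(e$indicator_id, levels = 1:6))
  cat("  per indicator:", paste(sprintf("%d:%d", 1:6, tab), collapse = " "), "\n")
  cat("  negation cues:", nrow(x$cues),
      " scope breakers:", length(x$scope_breakers), "\n")
  invisible(x)
}

#' Load a lexicon from a TSV or JSON file
#'
#' The TSV form has columns `surface`, `match_kind`, `script`,
#' `indicator_id`, `profiles` (comma-joined subset of `strict,relaxed`) and
#' `comment`; lines starting with `#` are comments. Negation cues are rows
#' with `match_kind` `"cue"` (`script` holds the direction `pre`/`post`,
#' `indicator_id` the token window) and scope breakers are rows with
#' `match_kind` `"breaker"`. The JSON form is the object written by
#' [write_lexicon()] with fields `entries`, `cues`, `scope_breakers`.
#'
#' @param path file path; format is inferred from the `.json` vs `.tsv`
#'   extension unless `format` is given.
#' @param format `"auto"`, `"tsv"` or `"json"`.
#' @return A validated [lexicon()] object.
#' @export
load_lexicon <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    return(lexicon(entries = obj$entries, cues = obj$cues,
                   scope_breakers = obj$scope_breakers))
  }
  raw <- utils::read.delim(path, comment.char = "#", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("surface", "match_kind", "script", "indicator_id", "profiles")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("lexicon file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(raw$comment)) raw$comment <- ""
  is_cue <- raw$match_kind == "cue"
  is_breaker <- raw$match_kind == "breaker"
  ent <- raw[!is_cue & !is_breaker, , drop = FALSE]
  profs <- strsplit(ent$profiles, ",", fixed = TRUE)
  bad <- vapply(profs, function(p) any(!trimws(p) %in% c("strict", "relaxed")),
                logical(1))
  if (any(bad)) {
    stop("unknown profile tag in row with surface ",
         sQuote(ent$surface[which(bad)[1L]]))
  }
  entries <- data.frame(
    surface = ent$surface,
    match_kind = ent$match_kind,
    script = ent$script,
    indicator_id = as.integer(ent$indicator_id),
    strict = vapply(profs, function(p) "strict" %in% trimws(p), logical(1)),
    relaxed = vapply(profs, function(p) "relaxed" %in% trimws(p), logical(1)),
    comment = ent$comment,
    stringsAsFactors = FALSE)
  cues <- data.frame(
    surface = raw$surface[is_cue],
    direction = raw$script[is_cue],
    window = as.integer(raw$indicator_id[is_cue]),
    stringsAsFactors = FALSE)
  lexicon(entries = entries, cues = cues,
          scope_breakers = raw$surface[is_breaker])
}

#' Write a lexicon to a TSV or JSON file
#'
#' @param x a [lexicon()] object.
#' @inheritParams load_lexicon
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(x, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(x, "spict_lexicon"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    jsonlite::write_json(
      list(entries = x$entries, cues = x$cues,
           scope_breakers = x$scope_breakers),
      path, auto_unbox = FALSE, digits = NA)
    return(invisible(path))
  }
  e <- x$entries
  profiles <- ifelse(e$strict, "strict,relaxed",
                     ifelse(e$relaxed, "relaxed", ""))
  rows <- data.frame(surface = e$surface, match_kind = e$match_kind,
                     script = e$script,
                     indicator_id = as.character(e$indicator_id),
                     profiles = profiles, comment = e$comment,
                     stringsAsFactors = FALSE)
  if (nrow(x$cues)) {
    rows <- rbind(rows, data.frame(
      surface = x$cues$surface, match_kind = "cue",
      script = x$cues$direction,
      indicator_id = as.character(x$cues$window),
      profiles = "", comment = "", stringsAsFactors = FALSE))
  }
  if (length(x$scope_breakers)) {
    rows <- rbind(rows, data.frame(
      surface = x$scope_breakers, match_kind = "breaker", script = "",
      indicator_id = "", profiles = "", comment = "",
      stringsAsFactors = FALSE))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled default English lexicon
#'
#' A small English dictionary for the six SPICT-LIS general indicators, with
#' nested strict/relaxed profiles. Surfaces are derived from the published
#' indicator definitions (e.g. the strict indicator-4 term
#' `"significant weight loss"` with relaxed-only expansions `"weight loss"`,
#' `"underweight"`, `"hyposthenic build"`, `"thinner"`) and from the common
#' persistent-symptom vocabulary (pain, dyspnea, edema, delirium,
#' xerostomia, ascites, dysphagia, anorexia). It is intentionally minimal
#' and fully replaceable: production deployments should supply a
#' site-specific dictionary via [load_lexicon()].
#'
#' @return A validated [lexicon()] object.
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "default_lexicon.tsv",
                      package = "spictminer", mustWork = TRUE)
  load_lexicon(path, format = "tsv")
}

#' Restrict a lexicon to one keyword profile
#'
#' Returns the lexicon containing only the entries visible to the requested
#' profile; negation cues and scope breakers are unchanged. Because strict
#' entries are nested inside relaxed entries, `profile_view(x, "strict")`
#' always yields a subset of `profile_view(x, "relaxed")`.
#'
#' @param x a [lexicon()] object.
#' @param profile `"strict"` or `"relaxed"`.
#' @return A [lexicon()] object.
#' @export
profile_view <- function(x, profile = c("strict", "relaxed")) {
  stopifnot(inherits(x, "spict_lexicon"))
  profile <- match.arg(profile)
  keep <- if (profile == "strict") x$entries$strict else x$entries$relaxed
  out <- x
  out$entries <- x$entries[keep, , drop = FALSE]
  rownames(out$entries) <- NULL
  out
}
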