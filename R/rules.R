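#' Aggregate polarized mentions into the six general indicators
#'
#' Indicator *i* is met iff at least one affirmed mention with
#' `indicator_id == i` exists; negated mentions never contribute. The
#' aggregation is existence-based: mention multiplicity and order are
#' irrelevant.
#'
#' @param mentions data.frame of polarized mentions
#'   (see [assign_polarity()]).
#' @return named logical vector of length 6 (`ind1`..`ind6`).
#' @export
evaluate_indicators <- function(mentions) {
  met <- logical(6)
  if (nrow(mentions)) {
    hit <- mentions$indicator_id[mentions$polarity == "affirmed"]
    met[unique(hit)] <- TRUE
  }
  names(met) <- paste0("ind", 1:6)
  met
}

#' Apply the palliative-care benefit decision rule
#'
#' A patient meets the screening criteria when at least `min_general` of
#' the six general indicators are met AND at least one clinical indicator
#' is met. For a cancer-registry cohort the confirmed cancer diagnosis
#' stands in for the clinical indicator, so `clinical_met` is normally the
#' registry confirmation flag.
#'
#' @param indicators logical vector of length 6 from
#'   [evaluate_indicators()].
#' @param clinical_met logical; whether at least one clinical indicator is
#'   met.
#' @param min_general minimum number of general indicators (default 2).
#' @param profile label recorded in the result (`"strict"`/`"relaxed"`).
#' @return list of class `spict_classification`: `profile`, `indicators`,
#'   `n_general_met`, `clinical_met`, `meets_criteria`.
#' @export
classify <- function(indicators, clinical_met, min_general = 2,
                     profile = NA_character_) {
  stopifnot(length(indicators) == 6L, is.logical(indicators),
            min_general >= 0)
  names(indicators) <- paste0("ind", 1:6)
  n_met <- sum(indicators)
  structure(
    list(profile = profile,
         indicators = indicators,
         n_general_met = n_met,
         clinical_met = isTRUE(clinical_met),
         meets_criteria = n_met >= min_general && isTRUE(clinical_met)),
    class = "spict_classification")
}

#' @export
print.spict_classification <- function(x, ...) {
  cat("SPICT-LIS screening (", x$profile, " profile)\n", sep = "")
  cat("  indicators met: ",
      if (x$n_general_met) paste(which(x$indicators), collapse = ", ")
      else "none", "\n", sep = "")
  cat("  general met: ", x$n_general_met,
      "  clinical met: ", x$clinical_met,
      "  meets criteria: ", x$meets_criteria, "\n", sep = "")
  invisible(x)
}

#' Screen one patient record
#'
#' Runs the full pipeline — [tokenize()], [find_mentions()],
#' [assign_polarity()], [evaluate_indicators()], [classify()] — on a single
#' record's note. `clinical_met` defaults to the record's
#' `cancer_confirmed` registry flag.
#'
#' @param record one-row data.frame (or list) with at least `note_text`;
#'   `cancer_confirmed` is used for the clinical indicator when present.
#' @param lex a [lexicon()] object.
#' @param profile `"strict"` or `"relaxed"`.
#' @param min_general minimum number of general indicators (default 2).
#' @param clinical_met override for the clinical indicator.
#' @return a `spict_classification` (see [classify()]).
#' @export
run_pipeline <- function(record, lex = default_lexicon(),
                         profile = c("strict", "relaxed"), min_general = 2,
                         clinical_met = NULL) {
  profile <- match.arg(profile)
  if (is.null(clinical_met)) {
    clinical_met <- if (!is.null(record$cancer_confirmed)) {
      isTRUE(as.logical(record$cancer_confirmed)[1])
    } else TRUE
  }
  toks <- tokenize(record$note_text[1], lex)
  mentions <- find_mentions_prepared(record$note_text[1], toks,
                                     prepare_matcher(lex, profile))
  mentions <- assign_polarity(mentions, toks, lex)
  classify(evaluate_indicators(mentions), clinical_met,
           min_general = min_general, profile = profile)
}

#' Screen a whole cohort
#'
#' Vectorized form of [run_pipeline()]: one row per patient with the
#' indicator booleans and the benefit decision.
#'
#' @param cohort data.frame of patient records (e.g. the `included` set
#'   from [filter_cohort()]).
#' @inheritParams run_pipeline
#' @return data.frame: `patient_id`, `profile`, `ind1`..`ind6` (0/1),
#'   `n_general_met`, `clinical_met`, `meets_criteria`.
#' @export
classify_cohort <- function(cohort, lex = default_lexicon(),
                            profile = c("strict", "relaxed"),
                            min_general = 2) {
  profile <- match.arg(profile)
  screen_cohort(cohort, lex, profiles = profile,
                min_general = min_general)[[profile]]
}

#' Screen a cohort under several profiles at once
#'
#' Like [classify_cohort()] but tokenizes each note only once and evaluates
#' all requested profiles on the shared token stream — the efficient way to
#' compare the strict and relaxed profiles on the same cohort.
#'
#' @inheritParams classify_cohort
#' @param profiles character vector, subset of `c("strict", "relaxed")`.
#' @return named list of classification data.frames, one per profile.
#' @export
screen_cohort <- function(cohort, lex = default_lexicon(),
                          profiles = c("strict", "relaxed"),
                          min_general = 2) {
  stopifnot(all(profiles %in% c("strict", "relaxed")), length(profiles) >= 1)
  matchers <- lapply(profiles, prepare_matcher, lex = lex)
  names(matchers) <- profiles
  seg <- segmentation_dict(lex)
  n <- nrow(cohort)
  ind_mats <- lapply(profiles, function(p) {
    matrix(FALSE, n, 6, dimnames = list(NULL, paste0("ind", 1:6)))
  })
  names(ind_mats) <- profiles
  for (i in seq_len(n)) {
    text <- cohort$note_text[i]
    toks <- tokenize_core(text, lex, seg)
    tok_lc <- stringi::stri_trans_tolower(toks$text)
    for (p in profiles) {
      mentions <- find_mentions_prepared(text, toks, matchers[[p]], tok_lc)
      mentions <- assign_polarity(mentions, toks, lex, tok_lc)
      ind_mats[[p]][i, ] <- evaluate_indicators(mentions)
    }
  }
  clinical <- if (!is.null(cohort$cancer_confirmed)) {
    as.logical(cohort$cancer_confirmed)
  } else rep(TRUE, n)
  clinical[is.na(clinical)] <- TRUE
  out <- lapply(profiles, function(p) {
    n_met <- rowSums(ind_mats[[p]])
    res <- data.frame(patient_id = cohort$patient_id,
                      profile = rep(p, n),
                      ind_mats[[p]] * 1L,
                      n_general_met = as.integer(n_met),
                      clinical_met = clinical,
                      meets_criteria = n_met >= min_general & clinical,
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
  })
  names(out) <- profiles
  out
}
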