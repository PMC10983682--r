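# Neutral Latin filler vocabulary. Kept disjoint from every default-lexicon
# surface token, negation cue and scope breaker so that planted evidence is
# the only source of indicator mentions (ground truth exact by construction);
# simulate_cohort() re-asserts the disjointness against the lexicon in use.
synth_filler_words <- c(
  "patient", "admitted", "ward", "today", "morning", "rounds", "chart",
  "reviewed", "vitals", "stable", "afebrile", "alert", "oriented", "diet",
  "tolerated", "medication", "given", "continued", "labs", "pending",
  "imaging", "scheduled", "nursing", "documented", "routine", "observation",
  "overnight", "hydration", "adequate", "ambulating", "hallway", "discharge",
  "planning", "discussed", "tomorrow", "clinic", "visit", "next", "week",
  "bloodwork", "ordered", "results", "awaited", "monitoring", "continues")

# Synthetic unsegmented-script mini-vocabulary (Greek-letter pseudo-words,
# deliberately not real clinical vocabulary in any language). Pseudo-words
# are concatenated without delimiters to emulate runs of an unsegmented
# script inside the notes.
synth_unseg_words <- c("αβε", "γδον",
                       "ζηλ", "θικα",
                       "μνω", "ξοπ",
                       "ρστυ", "φχψ")

#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the structure of a hospital cancer-registry cohort:
#' per-indicator prevalences follow the published relaxed-profile indicator
#' proportions, exclusion rates follow the published participant flow
#' (admission-before-diagnosis 2448/18203, short notes 765/18203,
#' non-malignant behavior 585/18203), and notes are long enough to pass the
#' 1000-word inclusion rule unless a short-note exclusion is planted.
#'
#' @param n_patients number of patients to generate.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param prevalence six probabilities, one per general indicator.
#' @param negated_mention_rate probability that an unmet indicator gets a
#'   planted negated term (noise the pipeline must ignore).
#' @param relaxed_only_rate probability that a met indicator's evidence is
#'   a relaxed-only term (invisible to the strict profile).
#' @param exclusion_rates named probabilities for
#'   `admission_before_diagnosis`, `note_too_short`,
#'   `non_malignant_behavior` (independent per patient).
#' @param script_mix fraction of filler positions written in the synthetic
#'   unsegmented script.
#' @param note_length_words length-2 integer range of note word counts for
#'   included notes.
#' @param min_general decision threshold used for the ground-truth benefit
#'   label.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 500,
                         seed = 1L,
                         prevalence = c(0.243, 0.238, 0.001, 0.176,
                                        0.003, 0.078),
                         negated_mention_rate = 0.2,
                         relaxed_only_rate = 0.3,
                         exclusion_rates = c(admission_before_diagnosis = 0.134,
                                             note_too_short = 0.042,
                                             non_malignant_behavior = 0.032),
                         script_mix = 0.1,
                         note_length_words = c(1050L, 1400L),
                         min_general = 2L) {
  stopifnot(n_patients >= 0, length(prevalence) == 6L)
  probs <- c(prevalence, negated_mention_rate, relaxed_only_rate,
             exclusion_rates, script_mix)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("all rates/probabilities must lie in [0, 1]")
  }
  need <- c("admission_before_diagnosis", "note_too_short",
            "non_malignant_behavior")
  if (!all(need %in% names(exclusion_rates))) {
    stop("exclusion_rates must be named: ", paste(need, collapse = ", "))
  }
  stopifnot(length(note_length_words) == 2L,
            note_length_words[1] <= note_length_words[2],
            min_general >= 0)
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         prevalence = prevalence,
         negated_mention_rate = negated_mention_rate,
         relaxed_only_rate = relaxed_only_rate,
         exclusion_rates = exclusion_rates[need],
         script_mix = script_mix,
         note_length_words = as.integer(note_length_words),
         min_general = as.integer(min_general)),
    class = "synth_config")
}

n_surface_words <- function(surface) lengths(strsplit(surface, "\\s+"))

# n_filler filler tokens split into 8-12-word sentences terminated by ".",
# with planted evidence sentences spliced in at random sentence boundaries
compose_note <- function(n_filler, planted, script_mix) {
  words <- character(0)
  if (n_filler > 0L) {
    unseg <- runif(n_filler) < script_mix
    words <- character(n_filler)
    words[!unseg] <- sample(synth_filler_words, sum(!unseg), replace = TRUE)
    k <- sum(unseg)
    if (k) {
      w <- sample(synth_unseg_words, k, replace = TRUE)
      lens <- sample(1:3, k, replace = TRUE)
      for (extra in 2:3) {
        add <- lens >= extra
        if (any(add)) {
          w[add] <- paste0(w[add], sample(synth_unseg_words, sum(add),
                                          replace = TRUE))
        }
      }
      words[unseg] <- w
    }
    sizes <- sample(8:12, ceiling(n_filler / 8), replace = TRUE)
    ends <- cumsum(sizes)
    ends <- c(ends[ends < n_filler], n_filler)
    words[ends] <- paste0(words[ends], ".")
  }
  if (length(planted)) {
    bounds <- c(0L, if (n_filler > 0L) which(endsWith(words, ".")))
    pos <- sample(bounds, length(planted), replace = TRUE)
    for (k in order(pos, decreasing = TRUE)) {
      words <- append(words, planted[k], after = pos[k])
    }
  }
  paste(words, collapse = " ")
}

#' Generate a synthetic cohort with exact ground truth
#'
#' For every patient a truth vector over the six general indicators is
#' sampled from `config$prevalence`. The note is composed of neutral filler
#' (disjoint from the lexicon, so it can never produce a mention) plus one
#' affirmed evidence term per met indicator — a relaxed-only term with
#' probability `relaxed_only_rate`, else a strict term — and, for unmet
#' indicators, a negated term (`"no <term>."`) at `negated_mention_rate`.
#' Records with planted exclusions (admission before diagnosis, short note,
#' ICD-O behavior 0/1) are generated at `exclusion_rates`. Demographics
#' (sex, religion, stage, dates) are sampled from realistic registry
#' proportions. Output is byte-identical across calls with the same config.
#'
#' @param config a [synth_config()].
#' @param lex lexicon used both to pick evidence terms and, later, to mine
#'   the notes; must provide at least one strict term per indicator (and one
#'   relaxed-only term per indicator when `relaxed_only_rate > 0`).
#' @return list with `records` (cohort data.frame as in [read_cohort()])
#'   and `truth` (data.frame: `patient_id`, `ind1`..`ind6`, `benefit`,
#'   `has_relaxed_only_evidence`, `excl_admission_before_diagnosis`,
#'   `excl_note_too_short`, `excl_non_malignant_behavior`).
#' @export
simulate_cohort <- function(config, lex = default_lexicon()) {
  stopifnot(inherits(config, "synth_config"))
  e <- lex$entries
  lit <- e[e$match_kind == "literal" & e$script == "segmented", , drop = FALSE]
  strict_terms <- split(lit$surface[lit$strict], lit$indicator_id[lit$strict])
  rel_only <- lit[lit$relaxed & !lit$strict, , drop = FALSE]
  rel_terms <- split(rel_only$surface, rel_only$indicator_id)
  for (i in as.character(1:6)) {
    if (is.null(strict_terms[[i]])) {
      stop("lexicon has no strict segmented term for indicator ", i)
    }
    if (config$relaxed_only_rate > 0 && is.null(rel_terms[[i]])) {
      stop("lexicon has no relaxed-only segmented term for indicator ", i)
    }
  }
  # filler must be inert: disjoint from surface tokens, cues and breakers
  surf_tokens <- unique(tolower(unlist(strsplit(e$surface, "\\s+"))))
  clash <- intersect(synth_filler_words,
                     c(surf_tokens, tolower(lex$cues$surface),
                       tolower(lex$scope_breakers)))
  if (length(clash)) {
    stop("filler vocabulary collides with lexicon: ",
         paste(clash, collapse = ", "))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_patients
  truth_mat <- matrix(runif(n * 6) < rep(config$prevalence, each = n),
                      nrow = n, ncol = 6)
  excl_adm <- runif(n) < config$exclusion_rates[["admission_before_diagnosis"]]
  excl_short <- runif(n) < config$exclusion_rates[["note_too_short"]]
  excl_behav <- runif(n) < config$exclusion_rates[["non_malignant_behavior"]]

  patient_id <- sprintf("P%05d", seq_len(n))
  diagnosis_date <- as.Date("2016-01-01") + sample(0:1826, n, replace = TRUE)
  admission_date <- diagnosis_date + sample(0:60, n, replace = TRUE)
  if (any(excl_adm)) {
    admission_date[excl_adm] <- diagnosis_date[excl_adm] -
      sample(30:400, sum(excl_adm), replace = TRUE)
  }
  birth_date <- diagnosis_date - sample(18:90, n, replace = TRUE) * 365L -
    sample(0:364, n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(0.539, 0.461))
  religion <- sample(c("buddhist", "islam", "other"), n, replace = TRUE,
                     prob = c(0.852, 0.143, 0.005))
  stage <- sample(c("1", "2", "3", "4", "unknown"), n, replace = TRUE,
                  prob = c(0.127, 0.151, 0.196, 0.266, 0.260))
  icd10 <- sample(c("C18", "C50", "C53", "C22", "C34", "C61", "C16"), n,
                  replace = TRUE)
  morph_base <- sample(c("8140", "8070", "8500", "9590"), n, replace = TRUE)
  behav <- ifelse(excl_behav,
                  sample(c("0", "1"), n, replace = TRUE),
                  sample(c("2", "3", "3", "3", "6", "9"), n, replace = TRUE))
  icdo_morphology <- if (n) paste0(morph_base, "/", behav) else character(0)

  note_text <- character(n)
  has_rel_only <- logical(n)
  for (p in seq_len(n)) {
    planted <- character(0)
    planted_tok <- 0L
    for (ind in 1:6) {
      key <- as.character(ind)
      if (truth_mat[p, ind]) {
        use_rel <- config$relaxed_only_rate > 0 &&
          runif(1) < config$relaxed_only_rate
        term <- if (use_rel) sample(rel_terms[[key]], 1)
                else sample(strict_terms[[key]], 1)
        if (use_rel) has_rel_only[p] <- TRUE
        planted <- c(planted, paste0(term, "."))
        planted_tok <- planted_tok + n_surface_words(term)
      } else if (runif(1) < config$negated_mention_rate) {
        all_terms <- c(strict_terms[[key]], rel_terms[[key]])
        term <- sample(all_terms, 1)
        planted <- c(planted, paste0("no ", term, "."))
        planted_tok <- planted_tok + n_surface_words(term) + 1L
      }
    }
    target <- if (excl_short[p]) sample(120:400, 1) else {
      sample(config$note_length_words[1]:config$note_length_words[2], 1)
    }
    n_filler <- max(0L, target - planted_tok)
    note_text[p] <- compose_note(n_filler, planted, config$script_mix)
  }

  records <- data.frame(
    patient_id = patient_id, birth_date = birth_date,
    diagnosis_date = diagnosis_date, admission_date = admission_date,
    sex = sex, religion = religion, stage = stage, icd10 = icd10,
    icdo_morphology = icdo_morphology, note_text = note_text,
    cancer_confirmed = rep(TRUE, n), stringsAsFactors = FALSE)
  class(records) <- c("spict_cohort", class(records))
  truth <- data.frame(
    patient_id = patient_id,
    truth_mat * 1L,
    benefit = rowSums(truth_mat) >= config$min_general,
    has_relaxed_only_evidence = has_rel_only,
    excl_admission_before_diagnosis = excl_adm,
    excl_note_too_short = excl_short,
    excl_non_malignant_behavior = excl_behav,
    stringsAsFactors = FALSE)
  names(truth)[2:7] <- paste0("ind", 1:6)
  list(records = records, truth = truth)
}

#' Expected strict/relaxed screening divergence
#'
#' Closed-form expectation of the fraction of patients flagged by the
#' relaxed profile but not by the strict profile, under the generator's
#' sampling model: indicator *i* is met independently with probability
#' `prevalence[i]` and, when met, its evidence is visible to the strict
#' profile with probability `1 - relaxed_only_rate`. The relaxed profile
#' detects every met indicator, so the divergence is
#' `P(M >= m) - P(S >= m)` where `M` counts met indicators, `S` counts
#' strict-visible ones and `m = min_general` (strict-flagged patients are a
#' subset of relaxed-flagged ones). Tail probabilities are
#' Poisson-binomial, computed by convolution.
#'
#' @param config a [synth_config()].
#' @return expected divergence fraction in `[0, 1]`.
#' @export
expected_divergence <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tail_ge <- function(probs, m) {
    dp <- 1
    for (pi in probs) dp <- c(dp * (1 - pi), 0) + c(0, dp * pi)
    if (m <= 0) 1 else sum(dp[seq.int(m + 1L, length(dp))])
  }
  m <- config$min_general
  p_relaxed <- tail_ge(config$prevalence, m)
  p_strict <- tail_ge(config$prevalence * (1 - config$relaxed_only_rate), m)
  p_relaxed - p_strict
}
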