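# Tiny ad-hoc lexicons and configs used across tests.

mini_lexicon <- function(surfaces, indicator_id = 1L, script = "segmented",
                         strict = TRUE, relaxed = TRUE,
                         match_kind = "literal",
                         cues = NULL, scope_breakers = character()) {
  lexicon(
    data.frame(surface = surfaces, match_kind = match_kind, script = script,
               indicator_id = indicator_id, strict = strict,
               relaxed = relaxed, stringsAsFactors = FALSE),
    cues = cues, scope_breakers = scope_breakers)
}

default_cues <- function() {
  data.frame(surface = c("no", "not", "denies", "without"),
             direction = "pre", window = 3L, stringsAsFactors = FALSE)
}

# generator configuration with all noise channels off (overridable via ...)
noise_free_config <- function(n, seed, ...) {
  args <- list(
    n_patients = n, seed = seed,
    relaxed_only_rate = 0, negated_mention_rate = 0,
    exclusion_rates = c(admission_before_diagnosis = 0, note_too_short = 0,
                        non_malignant_behavior = 0))
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

# one-row patient record with sensible defaults
make_record <- function(note_text, patient_id = "P1",
                        diagnosis_date = as.Date("2016-03-01"),
                        admission_date = as.Date("2016-03-05"),
                        icdo_morphology = "8140/3",
                        cancer_confirmed = TRUE) {
  data.frame(patient_id = patient_id,
             birth_date = as.Date("1950-01-01"),
             diagnosis_date = diagnosis_date,
             admission_date = admission_date,
             sex = "female", religion = "buddhist", stage = "3",
             icd10 = "C18", icdo_morphology = icdo_morphology,
             note_text = note_text, cancer_confirmed = cancer_confirmed,
             stringsAsFactors = FALSE)
}

# a note of exactly n words, none of which is a lexicon term
filler_note <- function(n) paste(rep("routine", n), collapse = " ")
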