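jl <- function(...) {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c(...), path)
  path
}

plain_df <- function(x) {
  class(x) <- "data.frame"
  rownames(x) <- NULL
  x
}

rec_json <- function(id, diag = "2016-03-01", adm = "2016-03-05",
                     morph = "8140/3") {
  sprintf(paste0(
    '{"patient_id":"%s","birth_date":"1950-01-01",',
    '"diagnosis_date":"%s","admission_date":"%s","sex":"female",',
    '"religion":"buddhist","stage":"3","icd10":["C18","C50"],',
    '"icdo_morphology":"%s","note_text":"stable overnight",',
    '"cancer_confirmed":true}'), id, diag, adm, morph)
}

test_that("JSONL cohorts read, preserve ids, and round-trip bit-exactly", {
  path <- jl(rec_json("A1"), rec_json("B2"), rec_json("C3", morph = "8140/0"))
  cohort <- read_cohort(path)
  expect_identical(nrow(cohort), 3L)
  expect_identical(cohort$patient_id, c("A1", "B2", "C3"))
  expect_identical(cohort$diagnosis_date, rep(as.Date("2016-03-01"), 3))
  expect_identical(cohort$icd10, rep("C18;C50", 3))
  expect_identical(behavior_digit(cohort$icdo_morphology), c(3L, 3L, 0L))
  out <- tempfile(fileext = ".jsonl")
  write_cohort(cohort, out)
  expect_identical(plain_df(read_cohort(out)), plain_df(cohort))
  # CSV round trip carries identical values
  out_csv <- tempfile(fileext = ".csv")
  write_cohort(cohort, out_csv)
  expect_identical(plain_df(read_cohort(out_csv)), plain_df(cohort))
  unlink(c(path, out, out_csv))
})

test_that("schema violations raise named errors", {
  path <- jl('{"patient_id":"A1","sex":"female","note_text":"x"}')
  expect_error(read_cohort(path), "birth_date")
  path2 <- jl(rec_json("A1"), rec_json("A1"))
  expect_error(read_cohort(path2), "duplicate patient_id")
  path3 <- jl(rec_json("A1", diag = "01/03/2016"))
  expect_error(read_cohort(path3), "diagnosis_date")
  # but the same file parses with an explicit fallback format
  expect_identical(
    read_cohort(path3, date_fallback = "%d/%m/%Y")$diagnosis_date,
    as.Date("2016-03-01"))
  unlink(c(path, path2, path3))
})

test_that("behavior digit parses from the string after the slash", {
  expect_identical(behavior_digit(c("8140/0", "8140/1", "8140/3", "9590/6")),
                   c(0L, 1L, 3L, 6L))
  expect_identical(behavior_digit(c(NA, "8140")), c(NA_integer_, NA_integer_))
  # out-of-range digits are rejected at read time
  path <- jl(rec_json("A1", morph = "8140/5"))
  expect_error(read_cohort(path), "behavior digit")
  unlink(path)
})

test_that("filter excludes admission-before-diagnosis, short notes and benign", {
  L <- default_lexicon()
  cohort <- rbind(
    make_record(filler_note(1200), patient_id = "ok"),
    make_record(filler_note(1200), patient_id = "early",
                diagnosis_date = as.Date("2016-03-01"),
                admission_date = as.Date("2016-01-01")),
    make_record(filler_note(999), patient_id = "short"),
    make_record(filler_note(1000), patient_id = "at_threshold"),
    make_record(filler_note(1200), patient_id = "benign",
                icdo_morphology = "8140/1"),
    make_record(filler_note(1200), patient_id = "same_day",
                diagnosis_date = as.Date("2016-03-05"),
                admission_date = as.Date("2016-03-05")))
  res <- filter_cohort(cohort, min_words = 1000, lex = L)
  expect_setequal(res$included$patient_id, c("ok", "at_threshold", "same_day"))
  ex <- res$report$exclusions
  expect_identical(ex$reason[ex$patient_id == "early"],
                   "ADMISSION_BEFORE_DIAGNOSIS")
  expect_identical(ex$reason[ex$patient_id == "short"], "NOTE_TOO_SHORT")
  expect_identical(ex$reason[ex$patient_id == "benign"],
                   "NON_MALIGNANT_BEHAVIOR")
  expect_identical(res$report$n_input, 6L)
  expect_identical(res$report$n_included, 3L)
})

test_that("records with a missing date are excluded with a parse flag", {
  cohort <- rbind(make_record(filler_note(1200), patient_id = "ok"),
                  make_record(filler_note(1200), patient_id = "nodate"))
  cohort$admission_date[2] <- NA
  res <- filter_cohort(cohort)
  expect_identical(res$included$patient_id, "ok")
  expect_identical(
    res$report$exclusions$reason[res$report$exclusions$patient_id == "nodate"],
    "MISSING_DATE")
})

test_that("filtering is idempotent and report arithmetic is consistent", {
  cfg <- synth_config(n_patients = 60, seed = 31,
                      note_length_words = c(1010L, 1100L))
  sim <- simulate_cohort(cfg)
  res <- filter_cohort(sim$records)
  again <- filter_cohort(res$included)
  expect_identical(again$included, res$included)
  expect_identical(again$report$n_included, again$report$n_input)
  n_excluded <- res$report$n_input - res$report$n_included
  expect_identical(length(unique(res$report$exclusions$patient_id)),
                   n_excluded)
  expect_gte(sum(res$report$counts), n_excluded)
})
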