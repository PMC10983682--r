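test_that("whitespace-delimited text splits into word and punct tokens", {
  L <- default_lexicon()
  toks <- tokenize("no pain today.", L)
  expect_identical(toks$text, c("no", "pain", "today", "."))
  expect_identical(toks$kind, c("word", "word", "word", "punct"))
  expect_identical(count_words("no pain today.", L), 3L)
  expect_identical(count_words("", L), 0L)
  expect_identical(nrow(tokenize("", L)), 0L)
})

test_that("unsegmented runs use greedy left-to-right longest match", {
  ul <- mini_lexicon(c("ab", "abc", "d"), script = "unsegmented")
  expect_identical(tokenize("abcd", ul)$text, c("abc", "d"))
  ul2 <- mini_lexicon("ab", script = "unsegmented")
  toks <- tokenize("abxz", ul2)
  expect_identical(toks$text, c("ab", "x", "z"))
  expect_identical(toks$kind, c("word", "unknown", "unknown"))
  ul3 <- mini_lexicon(c("ab", "cd"), script = "unsegmented")
  expect_identical(count_words("abcd", ul3), 2L)
})

test_that("token spans reconstruct the input for random mixed-script text", {
  ul <- mini_lexicon(c("αβ", "γδε"), script = "unsegmented")
  pieces <- c("alpha", "beta", "no", "pain,", "x.", "αβγδε", "ζηαβ", ";", "42")
  set.seed(2024)
  for (rep in 1:25) {
    text <- paste(sample(pieces, sample(3:12, 1), replace = TRUE),
                  collapse = " ")
    toks <- tokenize(text, ul)
    # every token is exactly the substring at its span
    expect_identical(toks$text,
                     substring(text, toks$start + 1L, toks$end))
    # spans are sorted and non-overlapping
    expect_true(all(diff(toks$start) > 0))
    expect_true(all(toks$start[-1] >= toks$end[-nrow(toks)]))
    # characters outside all spans are whitespace
    covered <- unlist(mapply(seq, toks$start + 1L, toks$end,
                             SIMPLIFY = FALSE))
    gaps <- setdiff(seq_len(nchar(text)), covered)
    expect_true(all(grepl("^\\s$", substring(text, gaps, gaps))))
  }
})

test_that("literal mentions respect profiles and match case-insensitively", {
  L <- default_lexicon()
  m <- find_mentions("significant weight loss noted", L, "strict")
  expect_identical(nrow(m), 1L)
  expect_identical(m$indicator_id, 4L)
  expect_identical(m$polarity, "affirmed")
  expect_identical(nrow(find_mentions("patient is underweight", L, "strict")),
                   0L)
  m2 <- find_mentions("patient is Underweight", L, "relaxed")
  expect_identical(m2$indicator_id, 4L)
  # punctuation interrupts a phrase
  expect_identical(
    nrow(find_mentions("significant weight. loss", L, "strict")), 0L)
})

test_that("strict mentions are a subset of relaxed mentions", {
  L <- default_lexicon()
  words <- c(L$entries$surface, "routine", "ward", "no", "but", ".")
  set.seed(99)
  for (rep in 1:20) {
    text <- paste(sample(words, 12, replace = TRUE), collapse = " ")
    ms <- find_mentions(text, L, "strict")
    mr <- find_mentions(text, L, "relaxed")
    key <- function(m) paste(m$indicator_id, m$start, m$end)
    expect_true(all(key(ms) %in% key(mr)))
  }
})

test_that("overlapping matches of one indicator resolve longest-first", {
  L <- default_lexicon()
  m <- find_mentions("significant weight loss", L, "relaxed")
  expect_identical(m$surface, "significant weight loss")
  # two disjoint occurrences both survive
  m2 <- find_mentions("weight loss then weight loss", L, "relaxed")
  expect_identical(nrow(m2), 2L)
})

test_that("regex entries match on raw text", {
  rl <- lexicon(data.frame(
    surface = "ecog [34]", match_kind = "regex", script = "segmented",
    indicator_id = 1, strict = TRUE, relaxed = TRUE))
  m <- find_mentions("ECOG 3 on admission", rl, "strict")
  expect_identical(nrow(m), 1L)
  expect_identical(m$indicator_id, 1L)
  expect_identical(m$start, 0L)
})

test_that("negation window and scope breakers behave as documented", {
  L <- default_lexicon()
  polarize <- function(text, profile = "relaxed") {
    toks <- tokenize(text, L)
    assign_polarity(find_mentions(text, L, profile), toks, L)
  }
  expect_identical(polarize("no pain")$polarity, "negated")
  expect_identical(polarize("pain")$polarity, "affirmed")
  # scope breaker between cue and mention keeps the mention affirmed
  m <- polarize("no fever but pain persists")
  expect_identical(m$surface, "pain")
  expect_identical(m$polarity, "affirmed")
  # cue beyond the 3-token window does not negate
  expect_identical(polarize("no history of severe chest pain")$polarity,
                   "affirmed")
  expect_identical(polarize("denies pain")$polarity, "negated")
  # sentence boundary cuts the scope
  expect_identical(polarize("no improvement. pain persists")$polarity,
                   "affirmed")
  # post-direction cue
  expect_identical(polarize("pain absent")$polarity, "negated")
  # negated multi-word strict phrase
  expect_identical(polarize("no significant weight loss", "strict")$polarity,
                   "negated")
})

test_that("literal matching agrees with a brute-force token-boundary scan", {
  vocab <- c("alpha", "bravo", "pain", "weight", "loss", "edema", "gamma")
  lex <- lexicon(data.frame(
    surface = c("pain", "weight loss", "edema"),
    match_kind = "literal", script = "segmented",
    indicator_id = c(5, 4, 5), strict = TRUE, relaxed = TRUE))
  brute_force <- function(text) {
    toks <- tokenize(text, lex)
    words <- tolower(toks$text)
    found <- list()
    for (i in seq_len(nrow(lex$entries))) {
      parts <- strsplit(tolower(lex$entries$surface[i]), " ")[[1]]
      L <- length(parts)
      for (s in seq_len(max(0, length(words) - L + 1))) {
        if (all(words[s:(s + L - 1)] == parts)) {
          found[[length(found) + 1L]] <-
            c(lex$entries$indicator_id[i], toks$start[s], toks$end[s + L - 1])
        }
      }
    }
    found
  }
  set.seed(7)
  for (rep in 1:30) {
    text <- paste(sample(vocab, sample(4:15, 1), replace = TRUE),
                  collapse = " ")
    m <- find_mentions(text, lex, "strict")
    got <- unname(split(as.matrix(m[, c("indicator_id", "start", "end")]),
                        seq_len(nrow(m))))
    want <- brute_force(text)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("the full mention pipeline is deterministic", {
  L <- default_lexicon()
  text <- "no pain today. significant weight loss. asks for palliative care"
  one <- assign_polarity(find_mentions(text, L, "relaxed"),
                         tokenize(text, L), L)
  two <- assign_polarity(find_mentions(text, L, "relaxed"),
                         tokenize(text, L), L)
  expect_identical(one, two)
})
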