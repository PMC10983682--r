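#' Tokenize clinical text against a lexicon
#'
#' Splits text into tokens with character spans. Runs delimited by
#' whitespace/punctuation are emitted as single `word` tokens. A run is
#' instead segmented by greedy left-to-right longest match (maximal
#' matching, the behavior of dictionary segmenters for scripts written
#' without word delimiters) when it shares characters with the alphabet of
#' the lexicon's `unsegmented` surfaces; characters of such a run matching
#' no dictionary surface become single-character tokens of kind `unknown`.
#' Punctuation characters are single tokens of kind `punct`.
#'
#' Spans are 0-based half-open character offsets into the input, so
#' concatenating token texts with the skipped whitespace reconstructs the
#' input exactly.
#'
#' @param text a single character string (Unicode; NFC-normalized
#'   internally).
#' @param lex a [lexicon()] object supplying the segmentation dictionary
#'   (entries with script `unsegmented` or `either`).
#' @return data.frame with columns `text`, `start`, `end`, `kind`
#'   (`word`/`unknown`/`punct`).
#' @export
tokenize <- function(text, lex = default_lexicon()) {
  as.data.frame(tokenize_core(text, lex), stringsAsFactors = FALSE)
}

# List-valued tokenizer used in cohort-scale loops (identical fields to
# tokenize() without data.frame overhead); `seg` may be precomputed with
# segmentation_dict().
tokenize_core <- function(text, lex, seg = segmentation_dict(lex)) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- list(text = character(), start = integer(), end = integer(),
                kind = character())
  if (is.na(text) || !nzchar(text)) return(empty)
  text <- stringi::stri_trans_nfc(text)
  m <- stringi::stri_locate_all_regex(
    text, "[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]")[[1]]
  if (anyNA(m[, 1])) return(empty)
  starts <- unname(m[, 1])
  lens <- unname(m[, 2] - m[, 1] + 1L)
  pieces <- stringi::stri_sub(text, starts, m[, 2])
  is_run <- stringi::stri_detect_regex(pieces, "^[\\p{L}\\p{N}]")
  needs_seg <- rep(FALSE, length(pieces))
  if (length(seg$alphabet)) {
    hit <- Reduce(`|`, lapply(seg$alphabet, function(ch) {
      stringi::stri_detect_fixed(pieces, ch)
    }))
    needs_seg <- is_run & hit
  }
  if (!any(needs_seg)) {
    return(list(text = pieces, start = starts - 1L,
                end = starts - 1L + lens,
                kind = c("punct", "word")[is_run + 1L]))
  }
  lst_text <- as.list(pieces)
  lst_start <- as.list(starts - 1L)
  lst_end <- as.list(starts - 1L + lens)
  lst_kind <- as.list(c("punct", "word")[is_run + 1L])
  for (i in which(needs_seg)) {
    sr <- segment_run(pieces[i], starts[i] - 1L, seg$surfaces)
    lst_text[[i]] <- sr$text
    lst_start[[i]] <- sr$start
    lst_end[[i]] <- sr$end
    lst_kind[[i]] <- sr$kind
  }
  list(text = unlist(lst_text, use.names = FALSE),
       start = unlist(lst_start, use.names = FALSE),
       end = unlist(lst_end, use.names = FALSE),
       kind = unlist(lst_kind, use.names = FALSE))
}

# Dictionary used for maximal matching: surfaces usable inside unsegmented
# runs, and the alphabet (characters of surfaces declared `unsegmented`)
# that flags a run as needing segmentation.
segmentation_dict <- function(lex) {
  e <- lex$entries
  lit <- e$match_kind == "literal"
  surfaces <- e$surface[lit & e$script %in% c("unsegmented", "either")]
  alpha_src <- e$surface[lit & e$script == "unsegmented"]
  alphabet <- unique(unlist(strsplit(alpha_src, "", fixed = TRUE)))
  alphabet <- setdiff(alphabet, c(" ", "\t"))
  list(surfaces = unique(surfaces), alphabet = alphabet)
}

# Greedy left-to-right longest match of `run` (offset0 = 0-based start of
# the run in the note) against dictionary `surfaces`; unmatched characters
# fall back to single-character `unknown` tokens.
segment_run <- function(run, offset0, surfaces) {
  n <- nchar(run)
  max_len <- if (length(surfaces)) max(nchar(surfaces)) else 0L
  texts <- character(); starts <- integer(); kinds <- character()
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (len in seq.int(min(max_len, n - i + 1L), 1L)) {
      if (len < 1L) break
      cand <- substr(run, i, i + len - 1L)
      if (cand %in% surfaces) { matched <- len; break }
    }
    if (matched > 0L) {
      texts <- c(texts, substr(run, i, i + matched - 1L))
      starts <- c(starts, i)
      kinds <- c(kinds, "word")
      i <- i + matched
    } else {
      texts <- c(texts, substr(run, i, i))
      starts <- c(starts, i)
      kinds <- c(kinds, "unknown")
      i <- i + 1L
    }
  }
  list(text = texts, start = offset0 + starts - 1L,
       end = offset0 + starts - 1L + nchar(texts), kind = kinds)
}

#' Count words in a note
#'
#' The number of non-punctuation tokens produced by [tokenize()]; used by
#' the cohort filter's minimum note length rule, so that the word count is
#' language-aware (an unsegmented-script run contributes as many words as
#' the dictionary segmentation yields).
#'
#' @inheritParams tokenize
#' @param note_text a single character string (may be empty or `NA`).
#' @return a non-negative integer.
#' @export
count_words <- function(note_text, lex = default_lexicon()) {
  if (is.na(note_text) || !nzchar(note_text)) return(0L)
  toks <- tokenize_core(note_text, lex)
  sum(toks$kind != "punct")
}

# Case-folded token text for matching (Latin case-insensitive after NFC).
fold <- function(x) stringi::stri_trans_tolower(stringi::stri_trans_nfc(x))

# Precompile a profile's entries against a fixed lexicon so that repeated
# find_mentions calls over a cohort avoid re-tokenizing surfaces.
prepare_matcher <- function(lex, profile) {
  view <- profile_view(lex, profile)
  e <- view$entries
  lit_idx <- which(e$match_kind == "literal")
  lit_tok <- lapply(lit_idx, function(i) {
    toks <- tokenize(e$surface[i], lex)
    fold(toks$text[toks$kind != "punct"])
  })
  list(entries = e, lit_idx = lit_idx, lit_tok = lit_tok,
       rex_idx = which(e$match_kind == "regex"))
}

find_mentions_prepared <- function(text, toks, matcher, tok_lc = NULL) {
  e <- matcher$entries
  # token texts come from NFC-normalized input, so case folding suffices
  if (is.null(tok_lc)) tok_lc <- stringi::stri_trans_tolower(toks$text)
  n_tok <- length(tok_lc)
  c_surface <- character(0); c_ind <- integer(0)
  c_start <- integer(0); c_end <- integer(0)
  c_tf <- integer(0); c_tl <- integer(0)
  for (k in seq_along(matcher$lit_idx)) {
    i <- matcher$lit_idx[k]
    seq_tok <- matcher$lit_tok[[k]]
    L <- length(seq_tok)
    if (L == 0L || n_tok < L) next
    hits <- which(tok_lc == seq_tok[1L])
    if (L > 1L) {
      hits <- hits[hits + L - 1L <= n_tok]
      for (j in seq_len(L - 1L)) {
        if (!length(hits)) break
        hits <- hits[tok_lc[hits + j] == seq_tok[j + 1L]]
      }
    }
    if (length(hits)) {
      c_surface <- c(c_surface, rep(e$surface[i], length(hits)))
      c_ind <- c(c_ind, rep(e$indicator_id[i], length(hits)))
      c_start <- c(c_start, toks$start[hits])
      c_end <- c(c_end, toks$end[hits + L - 1L])
      c_tf <- c(c_tf, hits)
      c_tl <- c(c_tl, hits + L - 1L)
    }
  }
  for (i in matcher$rex_idx) {
    m <- gregexpr(e$surface[i], text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    st <- as.integer(m) - 1L
    en <- st + attr(m, "match.length")
    tf <- vapply(st, function(s) {
      w <- which(toks$end > s); if (length(w)) w[1L] else NA_integer_
    }, integer(1))
    tl <- vapply(en, function(s) {
      w <- which(toks$start < s); if (length(w)) w[length(w)] else NA_integer_
    }, integer(1))
    keep <- !is.na(tf) & !is.na(tl)
    if (any(keep)) {
      c_surface <- c(c_surface, rep(e$surface[i], sum(keep)))
      c_ind <- c(c_ind, rep(e$indicator_id[i], sum(keep)))
      c_start <- c(c_start, st[keep])
      c_end <- c(c_end, en[keep])
      c_tf <- c(c_tf, tf[keep])
      c_tl <- c(c_tl, tl[keep])
    }
  }
  if (!length(c_surface)) {
    return(data.frame(surface = character(), indicator_id = integer(),
                      start = integer(), end = integer(),
                      tok_first = integer(), tok_last = integer(),
                      polarity = character(), stringsAsFactors = FALSE))
  }
  res <- data.frame(surface = c_surface, indicator_id = c_ind,
                    start = c_start, end = c_end,
                    tok_first = c_tf, tok_last = c_tl,
                    stringsAsFactors = FALSE)
  # overlap resolution within each indicator: longest first, then leftmost
  res <- res[order(res$indicator_id, -(res$end - res$start), res$start), ]
  keep <- logical(nrow(res))
  for (ind in unique(res$indicator_id)) {
    rows <- which(res$indicator_id == ind)
    taken_start <- integer(); taken_end <- integer()
    for (r in rows) {
      if (!any(res$start[r] < taken_end & res$end[r] > taken_start)) {
        keep[r] <- TRUE
        taken_start <- c(taken_start, res$start[r])
        taken_end <- c(taken_end, res$end[r])
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start, res$indicator_id), , drop = FALSE]
  res$polarity <- rep("affirmed", nrow(res))
  rownames(res) <- NULL
  res
}

#' Find lexicon mentions in a note
#'
#' Locates every occurrence of every profile-visible lexicon entry.
#' Literal entries are matched case-insensitively on the token sequence
#' (so punctuation interrupts a phrase); regex entries are matched on the
#' raw text. Overlapping matches for the same indicator are resolved
#' longest-first, then leftmost; mentions of different indicators may
#' overlap. Polarity is initialized to `affirmed` — apply
#' [assign_polarity()] to honor negation.
#'
#' @inheritParams tokenize
#' @param profile `"strict"` or `"relaxed"`.
#' @return data.frame of mentions: `surface`, `indicator_id`, `start`,
#'   `end` (0-based half-open character span), `tok_first`, `tok_last`
#'   (token indices), `polarity`.
#' @export
find_mentions <- function(text, lex = default_lexicon(),
                          profile = c("strict", "relaxed")) {
  profile <- match.arg(profile)
  toks <- tokenize(text, lex)
  find_mentions_prepared(text, toks, prepare_matcher(lex, profile))
}

#' Assign affirmed/negated polarity to mentions
#'
#' A mention is negated when a pre-direction negation cue occurs within its
#' token window before the mention's first token, with no scope breaker
#' (e.g. `"."`, `";"`, `"but"`) between cue and mention; symmetrically a
#' post-direction cue within its window after the mention's last token
#' negates it. All other mentions stay affirmed. This is the polarity step
#' that turns `"no pain"` into a negated pain mention while `"pain"` alone
#' stays affirmed.
#'
#' @param mentions data.frame from [find_mentions()].
#' @param toks data.frame from [tokenize()] on the same text.
#' @param lex the [lexicon()] supplying cues and scope breakers.
#' @return `mentions` with the `polarity` column updated.
#' @export
assign_polarity <- function(mentions, toks, lex = default_lexicon(),
                            tok_lc = NULL) {
  if (!nrow(mentions)) return(mentions)
  if (is.null(tok_lc)) tok_lc <- stringi::stri_trans_tolower(toks$text)
  breakers <- fold(lex$scope_breakers)
  cues <- lex$cues
  cue_lc <- fold(cues$surface)
  for (m in seq_len(nrow(mentions))) {
    f <- mentions$tok_first[m]
    l <- mentions$tok_last[m]
    negated <- FALSE
    for (ci in seq_len(nrow(cues))) {
      w <- cues$window[ci]
      if (cues$direction[ci] == "pre") {
        js <- seq.int(max(1L, f - w), f - 1L)
        js <- js[js >= 1L & js < f]
      } else {
        js <- seq.int(l + 1L, min(length(tok_lc), l + w))
        js <- js[js > l & js <= length(tok_lc)]
      }
      for (j in js) {
        if (tok_lc[j] != cue_lc[ci]) next
        between <- if (cues$direction[ci] == "pre") {
          if (j + 1L <= f - 1L) seq.int(j + 1L, f - 1L) else integer(0)
        } else {
          if (l + 1L <= j - 1L) seq.int(l + 1L, j - 1L) else integer(0)
        }
        if (!any(tok_lc[between] %in% breakers)) { negated <- TRUE; break }
      }
      if (negated) break
    }
    if (negated) mentions$polarity[m] <- "negated"
  }
  mentions
}
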