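---
title: "Screening clinical notes for palliative-care need: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening clinical notes for palliative-care need: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spictminer)
```

## The screening problem

The SPICT-LIS defines six condition-agnostic *general indicators* of
possible palliative-care need — deteriorating performance status,
dependence on others for care, carer strain, significant weight loss,
persistent symptoms despite treatment, and a patient/family request for
palliative care — plus disease-specific *clinical indicators*. A patient
is considered likely to benefit from palliative care when at least two
general indicators and at least one clinical indicator are met. For a
cancer-registry cohort the confirmed cancer diagnosis satisfies the
clinical side, so the screening task reduces to detecting the general
indicators in the free text of the first admission note written after the
diagnosis.

`spictminer` implements this as a dictionary-driven pipeline:

```
tokenize -> find_mentions -> assign_polarity -> evaluate_indicators -> classify
```

Each stage is exported and independently testable; `run_pipeline()` and
`classify_cohort()`/`screen_cohort()` compose them per record and per
cohort.

## The dictionary and the two profiles

A lexicon maps surfaces (literal phrases or regexes) to an indicator and
to one or both of two nested keyword *profiles*. The **strict** profile
holds only explicit, well-defined terms; the **relaxed** profile adds
broader synonyms. Nesting (`strict` implies `relaxed`) is a validity
invariant, so strict-flagged patients are provably a subset of
relaxed-flagged patients on any corpus — strict trades sensitivity for
specificity, relaxed the reverse, which is why a screening deployment
would run relaxed first and let clinicians adjudicate the
relaxed-but-not-strict band.

The bundled `default_lexicon()` is deliberately minimal: its surfaces are
derived from the published indicator definitions themselves (e.g.
indicator 4 strict = "significant weight loss", relaxed additions
"weight loss", "underweight", "hyposthenic build", "thinner") and from a
standard symptom vocabulary for indicator 5 (pain, dyspnea, edema,
delirium, xerostomia, ascites, dysphagia, anorexia). The original
deployment used a much larger mixed Thai/English dictionary that is not
publicly available; no attempt is made to reconstruct it, and the TSV/JSON
lexicon format (`load_lexicon()`, `write_lexicon()`) makes the dictionary
fully user-replaceable. Results with the bundled dictionary therefore
demonstrate the *mechanism*, not site-ready clinical coverage.

## Tokenization of mixed scripts

Clinical notes in this setting mix a whitespace-delimited script (English)
with an unsegmented script (Thai). The tokenizer splits
whitespace-delimited runs on whitespace/punctuation, and segments a run by
greedy left-to-right longest match (maximal matching) against the
dictionary when the run shares characters with the alphabet of the
lexicon's `unsegmented` surfaces; characters matching no surface fall back
to single-character `unknown` tokens. Greedy maximal matching was chosen
as the canonical segmentation because it is the documented default of the
classical Thai dictionary segmenters; a dynamic-programming variant
(fewest-words) is out of scope. Token spans are 0-based half-open
character offsets, and a property test asserts exact reconstruction of the
input from tokens plus whitespace.

The minimum-note-length cohort filter counts *non-punctuation tokens* from
this same tokenizer, so "1,000 words" means the same thing in both
scripts and the filter is reproducible from the data alone.

## Negation

The only polarity signal required of the pipeline is that an affirmed
symptom mention contributes to an indicator and a negated one never does
("no pain" must not count as pain). The implementation is a windowed cue
rule in token space: a pre-direction cue negates a mention when it occurs
within `window` tokens (default 3) before the mention's first token with
no scope breaker between them; post-direction cues work symmetrically.
Defaults — cues "no", "not", "denies", "denied", "without" (pre, window 3)
and "absent" (post, window 2); breakers ".", ";", "but" — are data in the
lexicon, not constants, because negation conventions vary across sites and
languages. The window length is a genuine design choice (the screening
rule itself only fixes the "no pain" behavior); 3 tokens is the common
default of window-based clinical negation rules, and the scope breakers
implement the observation that negation rarely crosses a clause boundary
("no fever but pain persists" affirms pain).

Overlapping dictionary matches of the *same* indicator are resolved
longest-first, then leftmost ("significant weight loss" wins over its
embedded "weight loss"); matches of different indicators may overlap
freely. Because indicator aggregation is existence-based (≥ 1 affirmed
mention; no counts or weights — nothing in the screening rule suggests
weighting), this resolution has no effect on decisions, only on mention
listings.

## The decision rule

`classify()` implements `meets_criteria = (n_general_met >= min_general)
AND clinical_met` with `min_general = 2` by default and `clinical_met`
taken from the record's cancer-registry confirmation flag. Both are
configurable: the threshold because the two-indicator rule is a published
convention rather than a law, and the clinical flag because non-registry
deployments may determine clinical indicators differently.

## Cohort filters

`filter_cohort()` excludes records with (i) admission strictly before
diagnosis, (ii) fewer than `min_words = 1000` words, (iii) ICD-O behavior
digit 0 or 1 (benign / uncertain behavior; digits 2, 3, 6, 9 are
retained). Records with a missing admission or diagnosis date are excluded
with the explicit flag `MISSING_DATE` rather than silently kept or
dropped. Two boundary decisions: equal admission and diagnosis dates are
*included* (only strictly earlier admissions are excluded), and the word
threshold is exclude-if-below-1000 — the operational reading of
"fewer than 1,000 words". A record may carry several reasons; the report
counts every reason but counts the patient once as excluded, so
`sum(counts) >= n_excluded` with equality when no record has two reasons.

## The synthetic-cohort generator

Because the hospital corpus is not public, validation runs on synthetic
cohorts with exact ground truth. `simulate_cohort()` draws, per patient, a
truth vector over the six indicators from a prevalence vector whose
default follows the published relaxed-profile indicator proportions
(24.3%, 23.8%, 0.1%, 17.6%, 0.3%, 7.8%); composes a note of neutral filler
plus one affirmed evidence sentence per met indicator; optionally plants
negated terms ("no <term>.") for unmet indicators (default rate 0.2); and
plants exclusion cases at the published participant-flow rates
(admission-before-diagnosis 2448/18203 ≈ 0.134, short notes 765/18203 ≈
0.042, non-malignant behavior 585/18203 ≈ 0.032). Included notes default
to 1,050–1,400 words so they clear the 1,000-word filter; planted short
notes are 120–400 words.

Three properties make the ground truth exact by construction:

* the filler vocabulary is disjoint from every lexicon surface token,
  negation cue and scope breaker (asserted at generation time), so filler
  can never create or negate a mention;
* each planted evidence term is its own sentence, so a preceding negated
  plant cannot leak scope into it;
* unsegmented-script filler is built from a synthetic Greek-letter
  mini-vocabulary — deliberately not real clinical vocabulary in any
  language — and each run counts as one word.

With probability `relaxed_only_rate` (default 0.3) a met indicator's
evidence uses a relaxed-only term, invisible to the strict profile. This
is the generator's model of why the two profiles diverge: strict
*under-detects* true cases whose evidence is phrased loosely. The
expected fraction of patients flagged by relaxed but not strict then has
the closed form `P(M >= m) - P(S >= m)`, with `M` Poisson-binomial over
the prevalences, `S` over prevalences times `(1 - relaxed_only_rate)`,
and `m = min_general` (`expected_divergence()`); simulations agree with it
within Monte-Carlo error. What the generator does **not** model is the
opposite failure mode observed with real dictionaries — relaxed terms
firing on incidental language and inflating false positives — nor real
clinical syntax, misspellings, section structure, or cross-sentence
negation. Passing the synthetic suite therefore demonstrates that the
mechanics (segmentation, matching, negation, aggregation, filtering,
statistics) are correct, not that the bundled dictionary would achieve any
particular accuracy on real notes.

## Statistics

Agreement between a screening run and reference labels is summarized by
percent agreement and Cohen's kappa, `κ = (p_o − p_e)/(1 − p_e)`, with
Cohen's large-sample standard error `sqrt(p_o(1−p_o)/(n(1−p_e)^2))` and a
95% Wald CI clipped to [−1, 1] (the CI method is this package's
choice). Interpretation bands:
> 0.7 good, 0.4–0.7 moderate, < 0.4 poor. Association measures follow
standard epidemiological practice: cross-product odds ratios with Wald
log-scale CIs and a flagged Haldane–Anscombe +0.5 correction for zero
cells, two-sided Fisher exact tests (delegated to `stats::fisher.test`
and verified in tests against an independent hypergeometric enumeration),
and logistic regression via `stats::glm` with explicit detection of
perfect separation. Prevalences are rounded half-up to one decimal to
match tabular reporting conventions; no multiple-testing adjustment is
applied (p < 0.05 is used as the conventional significance level).

## Problem sizes and numerical choices

The test suite validates label recovery on a 200-patient noise-free
cohort, monotonicity on twenty 500-patient cohorts, divergence and
prevalence calibration on 2,000-patient cohorts, kappa invariances on
1,000 random tables, and the Fisher oracle on 500 random tables with
n ≤ 40 — sizes chosen so every claim is exercised at scale while the full
suite runs in a couple of minutes. Where six binomial calibration checks
run simultaneously, the 99% bounds are Bonferroni-adjusted family-wise.
Literal matching is case-insensitive for Latin script after Unicode NFC
normalization and exact for other scripts. The generator restores the
caller's RNG state, so simulation is reproducible without side effects.

## Known limitations

* The bundled dictionary is a minimal English seed; real deployments must
  supply their own (the original mixed Thai/English dictionary is not
  public).
* Negation handling is windowed and lexical; hedges ("unlikely to be"),
  scope-changing syntax and cross-sentence anaphora are out of scope.
* Only the first post-diagnosis admission note is modeled; no temporal
  reasoning across admissions.
* The published cohort-level agreement figures depend on that private
  corpus and dictionary and are not reproducible here; the package
  validates the algorithmic machinery against synthetic ground truth and
  in-text arithmetic instead.
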