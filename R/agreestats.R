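#' Build a 2x2 confusion matrix from counts or labels
#'
#' Cell layout: `a` both raters positive, `b` rater 1 positive / rater 2
#' negative, `c` rater 1 negative / rater 2 positive, `d` both negative.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return object of class `confusion_2x2`.
#' @export
confusion_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  structure(as.list(counts), n = sum(counts), class = "confusion_2x2")
}

#' @rdname confusion_2x2
#' @param rater1,rater2 logical (or 0/1) vectors of equal length.
#' @export
confusion_from_labels <- function(rater1, rater2) {
  r1 <- as.logical(rater1); r2 <- as.logical(rater2)
  stopifnot(length(r1) == length(r2), !anyNA(r1), !anyNA(r2))
  confusion_2x2(sum(r1 & r2), sum(r1 & !r2), sum(!r1 & r2), sum(!r1 & !r2))
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(rater1 = c("pos", "neg"),
                              rater2 = c("pos", "neg")))
  print(m)
  invisible(x)
}

#' Percent agreement
#'
#' `100 * (a + d) / n`: the share of units on which the two raters agree.
#'
#' @param cm a [confusion_2x2()].
#' @return percentage in `[0, 100]`.
#' @export
percent_agreement <- function(cm) {
  n <- attr(cm, "n")
  if (n <= 0) stop("empty confusion matrix")
  100 * (cm$a + cm$d) / n
}

#' Cohen's kappa with large-sample confidence interval
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po = (a+d)/n` and expected agreement
#' `pe = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. The standard error uses Cohen's
#' large-sample formula `sqrt(po (1-po) / (n (1-pe)^2))` and the 95% CI is
#' `kappa +/- 1.96 se`, clipped to `[-1, 1]`.
#'
#' @param cm a [confusion_2x2()].
#' @return list `kappa`, `se`, `ci95` (length-2), `po`, `pe`.
#' @export
cohens_kappa <- function(cm) {
  n <- attr(cm, "n")
  if (n <= 0) stop("empty confusion matrix")
  a <- cm$a; b <- cm$b; c <- cm$c; d <- cm$d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (pe >= 1) stop("expected agreement is 1; kappa undefined")
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  ci <- kappa + c(-1, 1) * 1.96 * se
  list(kappa = kappa, se = se,
       ci95 = pmin(pmax(ci, -1), 1), po = po, pe = pe)
}

#' Interpretation band for a kappa value
#'
#' `> 0.7` good agreement, `0.4`–`0.7` moderate, `< 0.4` poor.
#'
#' @param kappa numeric in `[-1, 1]`.
#' @return `"good"`, `"moderate"` or `"poor"`.
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(kappa >= -1, kappa <= 1)
  if (kappa > 0.7) "good" else if (kappa >= 0.4) "moderate" else "poor"
}

#' Full agreement summary between two binary raters
#'
#' @inheritParams confusion_from_labels
#' @return list of class `agreement_result`: `confusion`,
#'   `percent_agreement`, `kappa`, `kappa_se`, `kappa_ci95`, `band`.
#' @export
agreement_stats <- function(rater1, rater2) {
  cm <- confusion_from_labels(rater1, rater2)
  k <- cohens_kappa(cm)
  structure(
    list(confusion = cm,
         percent_agreement = percent_agreement(cm),
         kappa = k$kappa, kappa_se = k$se, kappa_ci95 = k$ci95,
         band = interpret_kappa(min(max(k$kappa, -1), 1))),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("Inter-rater agreement (n = ", attr(x$confusion, "n"), ")\n", sep = "")
  cat(sprintf("  percent agreement: %.1f%%\n", x$percent_agreement))
  cat(sprintf("  Cohen's kappa:     %.2f (95%% CI %.2f-%.2f), %s agreement\n",
              x$kappa, x$kappa_ci95[1], x$kappa_ci95[2], x$band))
  invisible(x)
}

# round half-up to `digits` decimals (tables report 11.05 -> 11.1, not
# banker's rounding); a tiny relative epsilon absorbs float representation
# error of values that are exactly at .5 in decimal.
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9 * abs(x)) / s
}

#' Prevalence per 100 patients
#'
#' `100 * n_met / n_total`, rounded half-up to one decimal — the screening
#' yield as printed in prevalence tables.
#'
#' @param n_met number of patients meeting the criteria.
#' @param n_total cohort size (> 0).
#' @return numeric, one decimal.
#' @export
prevalence_per_100 <- function(n_met, n_total) {
  stopifnot(n_total > 0, n_met >= 0, n_met <= n_total)
  round_half_up(100 * n_met / n_total, 1)
}

#' Odds ratio for a 2x2 exposure-by-outcome table
#'
#' Cross-product ratio `OR = a d / (b c)` for the row-major table
#' `rbind(c(a, b), c(c, d))` (rows: exposure absent/present or level 1/2;
#' columns: outcome negative/positive — any consistent arrangement). The
#' 95% CI is Wald on the log scale. When any cell is zero the
#' Haldane–Anscombe correction (+0.5 to every cell) is applied and the
#' result is flagged `corrected = TRUE`.
#'
#' @param a,b,c,d non-negative cell counts (row-major).
#' @return list `or`, `ci95`, `corrected`.
#' @export
odds_ratio <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- counts[1] * counts[4] / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  list(or = or, ci95 = ci, corrected = corrected)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Sums, over all tables with the observed margins, the hypergeometric
#' probabilities no larger than that of the observed table (the convention
#' of [stats::fisher.test()], which performs the computation).
#'
#' @inheritParams odds_ratio
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  min(stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value, 1)
}

#' Logistic regression association with odds ratios
#'
#' Maximum-likelihood logistic fit of a binary outcome on one or more
#' covariates (categorical covariates reference-coded by R's factor
#' contrasts), reporting exponentiated coefficients with Wald 95%
#' confidence intervals and p-values. Perfect separation is detected and
#' raised as an error rather than returning a silently divergent fit.
#'
#' @param outcome binary (logical or 0/1) response vector.
#' @param covariates data.frame (or matrix) of covariates, one column per
#'   factor.
#' @return data.frame: `term`, `or`, `ci_lo`, `ci_hi`, `p` (intercept
#'   excluded).
#' @export
logistic_association <- function(outcome, covariates) {
  y <- as.numeric(as.logical(outcome))
  stopifnot(!anyNA(y), all(y %in% c(0, 1)))
  x <- as.data.frame(covariates, stringsAsFactors = FALSE)
  dat <- cbind(.outcome = y, x)
  fit <- suppressWarnings(
    stats::glm(.outcome ~ ., data = dat, family = stats::binomial()))
  coefs <- summary(fit)$coefficients
  slope <- coefs[rownames(coefs) != "(Intercept)", , drop = FALSE]
  if (!fit$converged || any(abs(slope[, "Estimate"]) > 15) ||
      any(slope[, "Std. Error"] > 1e3)) {
    stop("perfect (or quasi-perfect) separation: logistic estimates diverge")
  }
  data.frame(
    term = rownames(slope),
    or = exp(slope[, "Estimate"]),
    ci_lo = exp(slope[, "Estimate"] - 1.96 * slope[, "Std. Error"]),
    ci_hi = exp(slope[, "Estimate"] + 1.96 * slope[, "Std. Error"]),
    p = slope[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
}
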