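### Wald-ratio Mendelian randomization: convert a per-allele effect on
### ln(E2) and a published disease OR per doubling of E2 into a predicted
### per-allele disease OR, and test its compatibility with the observed OR.

#' Percent change per allele on the natural scale
#'
#' Back-transforms a regression slope on the natural-log scale:
#' `100 * (exp(beta) - 1)` percent per effect allele, with the 95 percent CI
#' `100 * (exp(beta +/- 1.96 se) - 1)`.
#'
#' @param beta slope on the natural-log scale.
#' @param se its standard error (must be > 0).
#' @return list with `percent` and `ci` (length 2).
#' @export
percent_per_allele <- function(beta, se) {
  if (se <= 0) stop("se must be positive")
  list(percent = 100 * (exp(beta) - 1),
       ci = 100 * (exp(beta + c(-1.96, 1.96) * se) - 1))
}

#' Predicted per-allele disease OR from the hormone effect
#'
#' The Wald-ratio prediction: an allele that multiplies E2 by `exp(beta)`
#' corresponds to `beta / ln 2` doublings of E2, so the predicted per-allele
#' OR is `exp(ln(or_doubling) * beta / ln 2)`. Equal to `or_doubling`
#' exactly when `beta = ln 2`, and 1 when `beta = 0`.
#'
#' @param beta per-allele slope on ln(E2).
#' @param or_doubling published disease OR per doubling of E2 (must be > 0);
#'   2.06 for endometrial cancer, 1.29 for breast cancer.
#' @return predicted per-allele OR.
#' @export
predict_or <- function(beta, or_doubling = 2.06) {
  if (or_doubling <= 0) stop("or_doubling must be positive")
  exp(log(or_doubling) * beta / log(2))
}

#' Delta-method CI for the predicted per-allele OR
#'
#' Treats the two inputs as independent sources of uncertainty:
#' `var(ln pred) = (beta/ln2)^2 var(ln or_doubling) +
#' (ln or_doubling / ln2)^2 se_beta^2`, with `var(ln or_doubling)` recovered
#' from its 95 percent CI as `((ln U - ln L)/(2*1.96))^2` (symmetric Wald
#' interval on the log scale). The CI is `exp(ln pred +/- 1.96 sqrt(var))`.
#'
#' @inheritParams predict_or
#' @param se_beta standard error of `beta` (>= 0).
#' @param ci_doubling length-2 CI `(lower, upper)` for `or_doubling`.
#' @return length-2 numeric `(lower, upper)`.
#' @export
predict_ci <- function(beta, se_beta, or_doubling = 2.06,
                       ci_doubling = c(1.47, 2.89)) {
  if (or_doubling <= 0) stop("or_doubling must be positive")
  if (ci_doubling[2] < ci_doubling[1]) stop("degenerate ci_doubling (U < L)")
  if (se_beta < 0) stop("se_beta must be non-negative")
  v_ln_or <- ((log(ci_doubling[2]) - log(ci_doubling[1])) / (2 * 1.96))^2
  v <- (beta / log(2))^2 * v_ln_or + (log(or_doubling) / log(2))^2 * se_beta^2
  lp <- log(or_doubling) * beta / log(2)
  exp(lp + c(-1.96, 1.96) * sqrt(v))
}

ci_to_se <- function(or, ci) {
  if (any(ci <= 0) || ci[2] < ci[1] || or < ci[1] || or > ci[2])
    stop("invalid CI: must be positive, ordered, and bracket the estimate")
  (log(ci[2]) - log(ci[1])) / (2 * 1.96)
}

#' Compatibility of observed and predicted odds ratios
#'
#' Standard errors are recovered from the 95 percent CIs on the log scale;
#' `z = (ln obs - ln pred) / sqrt(se_obs^2 + se_pred^2)` with a two-sided
#' normal P. The verdict is `"compatible"` when `p >= 0.05`.
#'
#' @param observed_or,observed_ci observed per-allele OR and its CI.
#' @param predicted_or,predicted_ci predicted OR and CI (e.g. from
#'   [predict_or()] / [predict_ci()]).
#' @return list with `z`, `p`, `verdict`.
#' @export
mr_compatibility <- function(observed_or, observed_ci,
                             predicted_or, predicted_ci) {
  se_o <- ci_to_se(observed_or, observed_ci)
  se_p <- ci_to_se(predicted_or, predicted_ci)
  if (se_o == 0 && se_p == 0) {
    z <- if (observed_or == predicted_or) 0 else Inf * sign(log(observed_or / predicted_or))
  } else z <- (log(observed_or) - log(predicted_or)) / sqrt(se_o^2 + se_p^2)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, verdict = if (p >= 0.05) "compatible" else "incompatible")
}

#' Phenotypic variance explained by a variant
#'
#' Additive Hardy-Weinberg variance of the dosage term relative to the total
#' phenotype variance: `100 * 2 f (1-f) beta^2 / var(phenotype)` percent.
#'
#' @param beta per-allele slope.
#' @param freq effect-allele frequency.
#' @param phenotype_variance total variance of the (log) phenotype (> 0).
#' @return percent of variance explained.
#' @export
variance_explained <- function(beta, freq, phenotype_variance) {
  if (phenotype_variance <= 0) stop("phenotype_variance must be positive")
  100 * 2 * freq * (1 - freq) * beta^2 / phenotype_variance
}

#' Wald-ratio Mendelian randomization report
#'
#' Combines the hormone-arm estimate (`beta`, `se` on ln E2) with the
#' external OR per doubling into the predicted per-allele disease OR and CI,
#' and compares it against the observed per-allele OR.
#'
#' @inheritParams predict_ci
#' @param observed_or,observed_ci observed per-allele disease OR with CI.
#' @param freq,phenotype_variance optional: effect-allele frequency and
#'   ln-phenotype variance for the variance-explained ancillary.
#' @return object of class `"mr_result"`: list with `beta`, `se`,
#'   `percent_per_allele`, `predicted_or`, `predicted_ci`, `observed_or`,
#'   `observed_ci`, `compat` (list `z`, `p`, `verdict`), and optionally
#'   `variance_explained`.
#' @export
mr_wald <- function(beta, se_beta, or_doubling = 2.06,
                    ci_doubling = c(1.47, 2.89),
                    observed_or = NULL, observed_ci = NULL,
                    freq = NULL, phenotype_variance = NULL) {
  res <- list(beta = beta, se = se_beta,
              percent_per_allele = percent_per_allele(beta, se_beta),
              or_doubling = or_doubling, ci_doubling = ci_doubling,
              predicted_or = predict_or(beta, or_doubling),
              predicted_ci = predict_ci(beta, se_beta, or_doubling, ci_doubling))
  if (!is.null(observed_or)) {
    res$observed_or <- observed_or
    res$observed_ci <- observed_ci
    res$compat <- mr_compatibility(observed_or, observed_ci,
                                   res$predicted_or, res$predicted_ci)
  }
  if (!is.null(freq) && !is.null(phenotype_variance))
    res$variance_explained <- variance_explained(beta, freq, phenotype_variance)
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, ...) {
  pp <- x$percent_per_allele
  cat(sprintf("Wald-ratio MR\n  per-allele effect on ln(E2): %.4f (se %.4f) = %+.1f%% (%.0f%% to %.0f%%)\n",
              x$beta, x$se, pp$percent, pp$ci[1], pp$ci[2]))
  cat(sprintf("  external OR per doubling of E2: %.2f (%.2f-%.2f)\n",
              x$or_doubling, x$ci_doubling[1], x$ci_doubling[2]))
  cat(sprintf("  predicted per-allele OR: %.3f (%.3f-%.3f)\n",
              x$predicted_or, x$predicted_ci[1], x$predicted_ci[2]))
  if (!is.null(x$observed_or)) {
    cat(sprintf("  observed per-allele OR:  %.3f (%.3f-%.3f)\n",
                x$observed_or, x$observed_ci[1], x$observed_ci[2]))
    cat(sprintf("  compatibility: z=%.3f, P=%.3f -> %s\n",
                x$compat$z, x$compat$p, x$compat$verdict))
  }
  if (!is.null(x$variance_explained))
    cat(sprintf("  variance in ln(E2) explained: %.2f%%\n", x$variance_explained))
  invisible(x)
}
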