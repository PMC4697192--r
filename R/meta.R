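### Fixed-effects inverse-variance meta-analysis with Cochran's Q, I-squared,
### and the heterogeneity exclusion rule applied in the regional scan.

#' Fixed-effects inverse-variance meta-analysis of one variant
#'
#' Pools per-study estimates with weights `w_i = 1/se_i^2`:
#' `beta_pooled = sum(w b) / sum(w)`, `se_pooled = sum(w)^(-1/2)`,
#' `Q = sum(w (b_i - beta_pooled)^2)` on `k - 1` df, and
#' `I2 = max(0, (Q - df)/Q) * 100`, the percent of variance attributable to
#' between-study heterogeneity. A single study passes through unchanged with
#' `Q = 0`, `df = 0`, `I2 = 0` and undefined heterogeneity P.
#'
#' @param studies data.frame with columns `study`, `beta`, `se` (one row per
#'   study; rows with non-finite `beta` or `se` are dropped).
#' @param variant_id optional variant label carried through.
#' @return object of class `"meta_result"`: list with `variant_id`,
#'   `beta_pooled`, `se_pooled`, `p_pooled` (two-sided Wald), `q_stat`, `df`,
#'   `p_het` (chi-square upper tail), `i2` (percent), `per_study`,
#'   `excluded_het` (`p_het < 0.05`).
#' @export
fixed_effects <- function(studies, variant_id = NA_character_) {
  if (is.null(studies) || nrow(studies) == 0) stop("no study results to pool")
  ok <- is.finite(studies$beta) & is.finite(studies$se) & studies$se > 0
  studies <- studies[ok, , drop = FALSE]
  k <- nrow(studies)
  if (k == 0) stop("no study with finite beta and se")
  w <- 1 / studies$se^2
  bp <- sum(w * studies$beta) / sum(w)
  sp <- sum(w)^-0.5
  q <- sum(w * (studies$beta - bp)^2)
  df <- k - 1L
  p_het <- if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_
  i2 <- if (df > 0 && q > 0) max(0, (q - df) / q) * 100 else 0
  res <- list(variant_id = variant_id, beta_pooled = bp, se_pooled = sp,
              p_pooled = 2 * stats::pnorm(-abs(bp / sp)),
              q_stat = q, df = df, p_het = p_het, i2 = i2,
              per_study = studies[, c("study", "beta", "se")],
              excluded_het = isTRUE(p_het < 0.05))
  class(res) <- "meta_result"
  res
}

#' @export
print.meta_result <- function(x, ...) {
  cat("meta_result", if (!is.na(x$variant_id)) paste0("[", x$variant_id, "]"),
      ": beta=", signif(x$beta_pooled, 4), " (se ", signif(x$se_pooled, 4),
      "), OR=", signif(exp(x$beta_pooled), 4),
      ", P=", format(x$p_pooled, digits = 3), "\n", sep = "")
  cat("  k=", x$df + 1, " studies, Q=", signif(x$q_stat, 4),
      ", I2=", round(x$i2, 1), "%, P_het=",
      ifelse(is.na(x$p_het), "NA", format(x$p_het, digits = 3)),
      if (x$excluded_het) "  [excluded: heterogeneity]", "\n", sep = "")
  invisible(x)
}

#' Meta-analyze per-study association scans across a region
#'
#' Applies [fixed_effects()] variant by variant over a list of per-study
#' [logistic_trend()] / [linear_assoc()] results. A variant is pooled over
#' whichever studies report a finite estimate for it (study panels may
#' differ).
#'
#' @param study_results named list of per-study association data.frames.
#' @return data.frame with one row per variant: pooled effect, `se`, `p`,
#'   `q_stat`, `df`, `p_het`, `i2`, `excluded_het`, plus `position`,
#'   `freq_case`/`freq_ctrl` averaged over studies (weighted by `n_used`).
#'   Per-study estimates are attached as attribute `"per_study"`.
#' @export
meta_scan <- function(study_results) {
  if (length(study_results) == 0) stop("no study results to pool")
  if (is.null(names(study_results)))
    names(study_results) <- paste0("study", seq_along(study_results))
  long <- do.call(rbind, lapply(names(study_results), function(s) {
    d <- study_results[[s]]; d$study <- s; d
  }))
  ids <- unique(long$variant_id)
  rows <- lapply(ids, function(v) {
    d <- long[long$variant_id == v, , drop = FALSE]
    m <- fixed_effects(d, variant_id = v)
    wn <- d$n_used / sum(d$n_used)
    data.frame(variant_id = v, position = d$position[1],
               beta = m$beta_pooled, se = m$se_pooled, p = m$p_pooled,
               q_stat = m$q_stat, df = m$df, p_het = m$p_het, i2 = m$i2,
               excluded_het = m$excluded_het,
               freq_case = sum(wn * d$freq_case),
               freq_ctrl = sum(wn * d$freq_ctrl),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$position), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "per_study") <- long
  res
}

#' Partition meta-analysis results by the heterogeneity rule
#'
#' Variants with significant between-study heterogeneity (`p_het < alpha`)
#' are flagged for exclusion from downstream fine-mapping; all others are
#' retained in their original order. Single-study variants have undefined
#' `p_het` and are retained with a warning rather than silently dropped.
#'
#' @param meta_results data.frame from [meta_scan()] (or any table with
#'   `p_het`).
#' @param alpha heterogeneity significance threshold, default 0.05.
#' @return list with elements `retained` and `excluded`.
#' @export
het_filter <- function(meta_results, alpha = 0.05) {
  stopifnot(alpha > 0)
  p <- meta_results$p_het
  if (any(is.na(p)))
    warning(sum(is.na(p)), " variant(s) with undefined heterogeneity P ",
            "(single study) retained")
  drop <- !is.na(p) & p < alpha
  list(retained = meta_results[!drop, , drop = FALSE],
       excluded = meta_results[drop, , drop = FALSE])
}
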