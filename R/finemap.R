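### Conditional scans, LD r2 on dosages, and the likelihood-ratio
### candidate-causal-variant set around the lead variant.

#' Pick the lead variant of a region
#'
#' The lead is the retained variant with the smallest pooled P value; ties
#' are broken by larger Wald chi-square `(beta/se)^2`, then by lower genomic
#' position.
#'
#' @param meta_results data.frame from [meta_scan()] (already
#'   heterogeneity-filtered if desired).
#' @return the lead `variant_id` (character scalar).
#' @export
pick_lead <- function(meta_results) {
  d <- meta_results
  if (!is.null(d$excluded_het)) d <- d[!d$excluded_het, , drop = FALSE]
  d <- d[is.finite(d$p), , drop = FALSE]
  if (nrow(d) == 0) stop("no retained variant to pick a lead from")
  chi2 <- (d$beta / d$se)^2
  d <- d[order(d$p, -chi2, d$position), , drop = FALSE]
  d$variant_id[1]
}

#' LD r-squared between two variants
#'
#' Squared Pearson correlation of the paired non-missing dosages (composite
#' LD, the measure available for unphased or imputed data). Symmetric, and
#' `ld_r2(g, a, a) = 1` for any polymorphic variant.
#'
#' @param genotypes a [geno_matrix()].
#' @param a,b variant ids.
#' @return r-squared in `[0, 1]`; `NA` with a warning if either variant is
#'   monomorphic on the paired samples.
#' @export
ld_r2 <- function(genotypes, a, b) {
  da <- dosage_of(genotypes, a); db <- dosage_of(genotypes, b)
  ok <- !is.na(da) & !is.na(db)
  if (stats::var(da[ok]) == 0 || stats::var(db[ok]) == 0) {
    warning("monomorphic variant in ld_r2(", a, ", ", b, ")")
    return(NA_real_)
  }
  stats::cor(da[ok], db[ok])^2
}

#' Conditional association scan adjusting for the lead variant
#'
#' Re-runs the per-variant association model with the lead variant's dosage
#' appended to the covariates, to ask whether any independent second signal
#' remains. The lead itself is skipped. A variant in perfect LD with the
#' lead is collinear in the joint fit and comes back as a flagged `NA` row.
#' The scan's verdict is "no second signal" when no conditional P falls at
#' or below `threshold_p`.
#'
#' @inheritParams logistic_trend
#' @param lead lead `variant_id` to condition on.
#' @param model `"logistic"` (case-control) or `"linear"` (hormone).
#' @param outcome outcome column (default `"status"` for logistic,
#'   `"log_e2t"` for linear).
#' @param threshold_p conditional significance cut-off, default `1e-4`.
#' @param robust passed to [linear_assoc()] for `model = "linear"`.
#' @return association data.frame (lead excluded) with attributes
#'   `"second_signal"` (logical) and `"threshold_p"`.
#' @export
conditional_scan <- function(genotypes, phenotypes, lead,
                             covariates = character(),
                             model = c("logistic", "linear"),
                             outcome = NULL, threshold_p = 1e-4,
                             robust = "none") {
  model <- match.arg(model)
  if (!lead %in% genotypes$variants$id) stop("lead '", lead, "' not found")
  if (is.null(outcome)) outcome <- if (model == "logistic") "status" else "log_e2t"
  lead_d <- dosage_of(genotypes, lead)
  ## refuse a lead that is collinear with an existing covariate
  for (cv in covariates) {
    x <- phenotypes[[cv]][match(genotypes$samples, phenotypes$sample_id)]
    if (is.numeric(x)) {
      ok <- !is.na(x) & !is.na(lead_d)
      if (sum(ok) > 2 && stats::var(x[ok]) > 0 && stats::var(lead_d[ok]) > 0 &&
          abs(stats::cor(x[ok], lead_d[ok])) > 1 - 1e-10)
        stop("lead variant is collinear with covariate '", cv, "'")
    }
  }
  ph <- phenotypes
  ph$.lead_dosage <- lead_d[match(ph$sample_id, genotypes$samples)]
  vars <- setdiff(genotypes$variants$id, lead)
  res <- if (model == "logistic") {
    logistic_trend(genotypes, ph, c(covariates, ".lead_dosage"), vars,
                   outcome = outcome)
  } else {
    linear_assoc(genotypes, ph, outcome, c(covariates, ".lead_dosage"),
                 robust = robust, variants = vars)
  }
  ## perfect proxies: lm/glm alias the dosage column -> flag as collinear
  attr(res, "second_signal") <- any(res$p <= threshold_p, na.rm = TRUE)
  attr(res, "threshold_p") <- threshold_p
  res
}

#' Likelihood-ratio candidate-causal-variant set
#'
#' Operationalizes the 1:100 rule on summary statistics: each variant's Wald
#' chi-square is `(beta/se)^2`, its likelihood ratio versus the index is
#' `LR_i = exp((chi2_index - chi2_i)/2)`, and the candidate set holds the
#' index plus every variant with `LR_i < lr_threshold` that is also in LD
#' with the index (`r2 > r2_threshold`). Members are sorted by ascending LR,
#' so the index (LR = 1) always comes first.
#'
#' @param meta_results data.frame from [meta_scan()] with `beta`, `se`.
#' @param genotypes a [geno_matrix()] used for the r-squared filter.
#' @param index index (lead) `variant_id`; must appear in `meta_results`.
#' @param lr_threshold likelihood-ratio threshold, default 100.
#' @param r2_threshold LD threshold, default 0.2.
#' @return object of class `"candidate_set"`: list with `index_variant`,
#'   `members` (data.frame `variant_id`, `chi2`, `lr`, `r2`), and the two
#'   thresholds.
#' @export
candidate_set <- function(meta_results, genotypes, index,
                          lr_threshold = 100, r2_threshold = 0.2) {
  d <- meta_results
  if (!index %in% d$variant_id) stop("index '", index, "' not in results")
  chi2 <- (d$beta / d$se)^2
  chi_idx <- chi2[d$variant_id == index]
  lr <- exp((chi_idx - chi2) / 2)
  r2 <- vapply(d$variant_id, function(v)
    if (v == index) 1.0 else suppressWarnings(ld_r2(genotypes, v, index)),
    numeric(1))
  keep <- (d$variant_id == index) |
    (!is.na(lr) & lr < lr_threshold & !is.na(r2) & r2 > r2_threshold)
  members <- data.frame(variant_id = d$variant_id, chi2 = chi2, lr = lr,
                        r2 = r2, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  members <- members[order(members$lr, members$variant_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(index_variant = index, members = members,
                 lr_threshold = lr_threshold, r2_threshold = r2_threshold),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set: index ", x$index_variant, ", ", nrow(x$members),
      " member(s) (LR < ", x$lr_threshold, ", r2 > ", x$r2_threshold, ")\n",
      sep = "")
  print(utils::head(x$members, 10), row.names = FALSE)
  if (nrow(x$members) > 10) cat("  ... ", nrow(x$members) - 10, " more\n")
  invisible(x)
}
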