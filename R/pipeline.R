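### The end-to-end regional analysis, exposed in the classic R modelling
### idiom: one fitting function returning a classed object with print /
### summary / coef / plot methods.

#' Analysis thresholds
#'
#' @param genome_wide genome-wide significance threshold (default `5e-8`).
#' @param conditional secondary/conditional significance cut-off (`1e-4`).
#' @param het_alpha between-study heterogeneity exclusion level (`0.05`).
#' @param lr likelihood-ratio threshold of the candidate set (`100`).
#' @param r2 LD threshold of the candidate set (`0.2`).
#' @return named list of thresholds.
#' @export
regmr_thresholds <- function(genome_wide = 5e-8, conditional = 1e-4,
                             het_alpha = 0.05, lr = 100, r2 = 0.2) {
  th <- list(genome_wide = genome_wide, conditional = conditional,
             het_alpha = het_alpha, lr = lr, r2 = r2)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  th
}

#' Fit the full regional variant-to-hormone-to-disease analysis
#'
#' Runs the whole chain on one genomic region: per-study per-allele logistic
#' scans of case-control status, fixed-effects meta-analysis with the
#' heterogeneity exclusion rule, lead-variant selection, a conditional scan
#' for independent second signals, the likelihood-ratio / LD candidate-
#' causal-variant set, quartile-stratified estimates with the 1-df
#' genotype-by-BMI interaction test, the hormone-arm linear model at the
#' lead variant, and the Wald-ratio Mendelian-randomization comparison of
#' predicted versus observed per-allele disease OR.
#'
#' @param genotypes a [geno_matrix()] covering all samples (cases, controls
#'   and the hormone cohort).
#' @param phenotypes phenotype data.frame (schema of [simulate_hormones()]);
#'   disease samples need `status` 0/1, hormone samples non-missing
#'   `log_e2`.
#' @param disease_covariates covariates of the case-control scans (per
#'   study), default none.
#' @param hormone_covariates adjustment set of the hormone-arm scan.
#' @param mr_covariates reduced adjustment set (study and laboratory batch
#'   only) used to re-estimate the per-allele E2 effect feeding the MR
#'   prediction.
#' @param hormone_outcome outcome of the hormone scan (default `"log_e2"`).
#' @param strata_variable quartile-stratification variable (default
#'   `"bmi"`); strata of the disease model are adjusted for age.
#' @param or_doubling,ci_doubling external disease OR per doubling of E2.
#' @param thresholds a [regmr_thresholds()] list.
#' @param cluster_robust use cluster-sandwich standard errors in hormone
#'   models (requires a `cluster_id` column).
#' @return object of class `"regmr"`: list with components `meta`
#'   (region-wide pooled results), `het` (retained/excluded split), `lead`,
#'   `conditional`, `candidates`, `strata_disease`, `strata_hormone`,
#'   `hormone` (lead-variant hormone association), `mr` (the
#'   [mr_wald()] report), `thresholds`, and `n` (sample bookkeeping).
#' @seealso [print.regmr()], [summary.regmr()], [plot.regmr()]
#' @export
regmr <- function(genotypes, phenotypes,
                  disease_covariates = character(),
                  hormone_covariates = c("age", "bmi", "hrt", "menopause",
                                         "batch", "study"),
                  mr_covariates = c("study", "batch"),
                  hormone_outcome = "log_e2",
                  strata_variable = "bmi",
                  or_doubling = 2.06, ci_doubling = c(1.47, 2.89),
                  thresholds = regmr_thresholds(),
                  cluster_robust = TRUE) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  ph <- phenotypes
  is_cc <- !is.na(ph$status)
  is_horm <- !is.na(ph$log_e2)
  if (!any(is_cc)) stop("no case-control samples (all status missing)")

  ## 1. per-study scans + fixed-effects meta-analysis
  cc <- ph[is_cc, , drop = FALSE]
  studies <- unique(cc$study)
  per_study <- lapply(studies, function(s) {
    phs <- cc[cc$study == s, , drop = FALSE]
    logistic_trend(subset_geno(genotypes, phs$sample_id), phs,
                   disease_covariates)
  })
  names(per_study) <- studies
  meta <- meta_scan(per_study)
  het <- het_filter(meta, thresholds$het_alpha)

  ## 2. lead variant, conditional scan, candidate set
  lead <- pick_lead(het$retained)
  cc_geno <- subset_geno(genotypes, cc$sample_id)
  conditional <- conditional_scan(cc_geno, cc, lead, disease_covariates,
                                  model = "logistic",
                                  threshold_p = thresholds$conditional)
  candidates <- candidate_set(het$retained, cc_geno, lead,
                              lr_threshold = thresholds$lr,
                              r2_threshold = thresholds$r2)

  ## 3. quartile stratification + interaction (disease and hormone arms)
  strata_disease <- strata_hormone <- NULL
  spec <- NULL
  has_strat <- strata_variable %in% names(ph) &&
    sum(!is.na(cc[[strata_variable]]) & cc$status == 1) >= 4
  if (has_strat) {
    spec <- case_quartiles(cc, strata_variable)
    strata_disease <- tryCatch(
      stratified_assoc(cc_geno, cc, spec, lead, model = "logistic",
                       covariates = intersect("age", names(cc))),
      error = function(e) { warning("disease strata skipped: ",
                                    conditionMessage(e)); NULL })
    if (any(is_horm)) {
      hp <- ph[is_horm, , drop = FALSE]
      strata_hormone <- tryCatch(
        stratified_assoc(subset_geno(genotypes, hp$sample_id), hp, spec, lead,
                         model = "linear", outcome = "log_e2",
                         covariates = setdiff(hormone_covariates,
                                              strata_variable),
                         robust = if (cluster_robust) "cluster" else "none"),
        error = function(e) { warning("hormone strata skipped: ",
                                      conditionMessage(e)); NULL })
    }
  }

  ## 4. hormone arm at the lead + Wald-ratio MR
  hormone <- mr <- NULL
  if (any(is_horm)) {
    hp <- ph[is_horm, , drop = FALSE]
    hg <- subset_geno(genotypes, hp$sample_id)
    rb <- if (cluster_robust && "cluster_id" %in% names(hp)) "cluster" else "none"
    hormone <- linear_assoc(hg, hp, hormone_outcome,
                            intersect(hormone_covariates, names(hp)),
                            robust = rb, variants = lead)
    mr_fit <- linear_assoc(hg, hp, hormone_outcome,
                           intersect(mr_covariates, names(hp)),
                           robust = rb, variants = lead)
    obs <- meta[meta$variant_id == lead, ]
    mr <- mr_wald(mr_fit$beta, mr_fit$se, or_doubling, ci_doubling,
                  observed_or = exp(obs$beta),
                  observed_ci = exp(obs$beta + c(-1.96, 1.96) * obs$se),
                  freq = mr_fit$freq,
                  phenotype_variance = stats::var(hp[[hormone_outcome]],
                                                  na.rm = TRUE))
  }

  structure(list(meta = meta, het = het, lead = lead,
                 conditional = conditional, candidates = candidates,
                 quartiles = spec,
                 strata_disease = strata_disease,
                 strata_hormone = strata_hormone,
                 hormone = hormone, mr = mr, thresholds = thresholds,
                 per_study = per_study,
                 n = list(cases = sum(cc$status == 1),
                          controls = sum(cc$status == 0),
                          hormone = sum(is_horm),
                          variants = nrow(genotypes$variants),
                          studies = length(studies))),
            class = "regmr")
}

#' @export
print.regmr <- function(x, ...) {
  obs <- x$meta[x$meta$variant_id == x$lead, ]
  cat("Regional association / fine-mapping / MR analysis\n")
  cat(sprintf("  %d variants; %d cases / %d controls in %d studies; hormone n=%d\n",
              x$n$variants, x$n$cases, x$n$controls, x$n$studies, x$n$hormone))
  cat(sprintf("  heterogeneity-excluded variants: %d of %d\n",
              nrow(x$het$excluded), nrow(x$meta)))
  cat(sprintf("  lead %s: OR=%.3f (%.3f-%.3f), P=%.3g, I2=%.1f%%, P_het=%s\n",
              x$lead, exp(obs$beta), exp(obs$beta - 1.96 * obs$se),
              exp(obs$beta + 1.96 * obs$se), obs$p, obs$i2,
              ifelse(is.na(obs$p_het), "NA", format(obs$p_het, digits = 2))))
  ss <- attr(x$conditional, "second_signal")
  cat(sprintf("  conditional scan: %s (threshold P<=%g)\n",
              if (isTRUE(ss)) "second signal detected" else "no second signal",
              x$thresholds$conditional))
  cat(sprintf("  candidate causal set: %d variants (LR<%g, r2>%g)\n",
              nrow(x$candidates$members), x$thresholds$lr, x$thresholds$r2))
  if (!is.null(x$hormone))
    cat(sprintf("  lead effect on %s: beta=%.4f (se %.4f), P=%.3g\n",
                "ln(E2)", x$hormone$beta, x$hormone$se, x$hormone$p))
  if (!is.null(x$mr))
    cat(sprintf("  MR: predicted OR %.3f (%.3f-%.3f) vs observed %.3f -> %s (P=%.2f)\n",
                x$mr$predicted_or, x$mr$predicted_ci[1], x$mr$predicted_ci[2],
                x$mr$observed_or, x$mr$compat$verdict, x$mr$compat$p))
  invisible(x)
}

#' @export
summary.regmr <- function(object, ...) {
  structure(list(fit = object), class = "summary.regmr")
}

#' @export
print.summary.regmr <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat("\nTop pooled associations:\n")
  top <- f$meta[order(f$meta$p), ][seq_len(min(5, nrow(f$meta))), ]
  print(data.frame(variant = top$variant_id, OR = round(exp(top$beta), 3),
                   P = signif(top$p, 3), I2 = round(top$i2, 1)),
        row.names = FALSE)
  if (!is.null(f$strata_disease)) {
    cat("\nDisease association by", f$quartiles$variable, "quartile:\n")
    print(f$strata_disease)
  }
  if (!is.null(f$mr)) { cat("\n"); print(f$mr) }
  invisible(x)
}

#' @export
coef.regmr <- function(object, ...) {
  stats::setNames(object$meta$beta, object$meta$variant_id)
}

#' Regional association plot
#'
#' Position versus -log10 pooled P, with the lead variant and candidate-set
#' members highlighted and the genome-wide and conditional thresholds drawn.
#'
#' @param x a [regmr()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.regmr <- function(x, ...) {
  d <- x$meta
  lp <- -log10(d$p)
  in_set <- d$variant_id %in% x$candidates$members$variant_id
  graphics::plot(d$position / 1e6, lp, pch = 20,
                 col = ifelse(d$variant_id == x$lead, "red",
                              ifelse(in_set, "orange", "grey40")),
                 xlab = "position (Mb)", ylab = expression(-log[10](P)), ...)
  graphics::abline(h = -log10(x$thresholds$genome_wide), lty = 2, col = "red")
  graphics::abline(h = -log10(x$thresholds$conditional), lty = 3, col = "grey60")
  graphics::legend("topright", pch = 20, bty = "n",
                   col = c("red", "orange", "grey40"),
                   legend = c("lead", "candidate set", "other"))
  invisible(x)
}
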