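### Case-distribution quartiles, stratified association estimates and the
### 1-df genotype-by-stratum interaction trend test.

#' Quartile specification from the case distribution
#'
#' Cutpoints are the 25/50/75 empirical percentiles (linear interpolation,
#' `quantile` type 7) of the variable's distribution in cases, so the four
#' strata carry roughly equal numbers of cases and hence comparable
#' statistical power. The same specification is reused for the hormone
#' analysis so disease and hormone strata are directly comparable.
#'
#' @param phenotypes phenotype data.frame with `status` and the variable.
#' @param variable `"bmi"` or `"age"` (any numeric column is accepted).
#' @return object of class `"quartile_spec"`: list with `variable`,
#'   `cutpoints` (ascending length 3) and `labels` `Q1..Q4`.
#' @export
case_quartiles <- function(phenotypes, variable = c("bmi", "age")) {
  variable <- if (is.character(variable)) variable[1] else match.arg(variable)
  if (!variable %in% names(phenotypes)) stop("no '", variable, "' column")
  x <- phenotypes[[variable]][phenotypes$status %in% 1]
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("need at least 4 non-missing case values of ", variable)
  cuts <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  if (any(diff(cuts) <= 0)) stop("degenerate quartile cutpoints for ", variable)
  structure(list(variable = variable, cutpoints = cuts,
                 labels = paste0("Q", 1:4)), class = "quartile_spec")
}

#' @export
print.quartile_spec <- function(x, ...) {
  cat("quartile_spec for ", x$variable, ": cutpoints ",
      paste(signif(x$cutpoints, 4), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Assign samples to quartiles
#'
#' Intervals are left-closed/right-open, `[-Inf, c1) [c1, c2) [c2, c3)
#' [c3, Inf)`, i.e. a value exactly on a cutpoint belongs to the stratum
#' above it (Q4 is closed below).
#'
#' @param values numeric vector.
#' @param spec a [case_quartiles()] specification.
#' @return integer vector of quartile numbers 1-4 (`NA` for missing values).
#' @export
assign_quartiles <- function(values, spec) {
  stopifnot(inherits(spec, "quartile_spec"))
  findInterval(values, spec$cutpoints) + 1L
}

#' Stratified association estimates by quartile
#'
#' Fits the per-allele association model separately within each quartile of
#' the specification. For disease models stratified by BMI the convention is
#' to adjust each stratum for age (pass `covariates = "age"`); hormone
#' analyses in strata use log E2 uncorrected for testosterone to maximize
#' sample size.
#'
#' @inheritParams logistic_trend
#' @param spec a [case_quartiles()] specification.
#' @param variant single variant id to test.
#' @param model `"logistic"` or `"linear"`.
#' @param outcome outcome column (default by model).
#' @param min_n minimum per-stratum sample size; smaller strata raise a
#'   warning, empty strata an error naming the stratum.
#' @param robust passed to [linear_assoc()].
#' @return object of class `"strata_result"`: list with `spec`, `strata`
#'   (association data.frame with a `stratum` column and per-stratum counts)
#'   and `interaction` (the [interaction_test()] result).
#' @export
stratified_assoc <- function(genotypes, phenotypes, spec, variant,
                             model = c("logistic", "linear"),
                             covariates = character(), outcome = NULL,
                             min_n = 50, robust = "none") {
  model <- match.arg(model)
  stopifnot(inherits(spec, "quartile_spec"))
  if (is.null(outcome)) outcome <- if (model == "logistic") "status" else "log_e2"
  q <- assign_quartiles(phenotypes[[spec$variable]], spec)
  rows <- vector("list", 4)
  for (k in 1:4) {
    keep <- !is.na(q) & q == k
    if (!any(keep)) stop("empty stratum ", spec$labels[k], " of ", spec$variable)
    if (sum(keep) < min_n)
      warning("stratum ", spec$labels[k], " has only ", sum(keep), " samples")
    ph <- phenotypes[keep, , drop = FALSE]
    gm <- subset_geno(genotypes, ph$sample_id)
    r <- if (model == "logistic") {
      logistic_trend(gm, ph, covariates, variants = variant, outcome = outcome)
    } else {
      linear_assoc(gm, ph, outcome, covariates, robust = robust,
                   variants = variant)
    }
    r$stratum <- spec$labels[k]
    r$n_stratum <- sum(keep)
    rows[[k]] <- r
  }
  inter <- interaction_test(genotypes, phenotypes, spec, variant,
                            model = model, covariates = covariates,
                            outcome = outcome, robust = robust)
  structure(list(spec = spec, strata = do.call(rbind, rows),
                 interaction = inter), class = "strata_result")
}

#' @export
print.strata_result <- function(x, ...) {
  cat("strata_result by ", x$spec$variable, " quartile:\n", sep = "")
  d <- x$strata
  est <- if (d$model[1] == "logistic")
    sprintf("OR=%.3f (%.3f-%.3f)", exp(d$beta), exp(d$beta - 1.96 * d$se),
            exp(d$beta + 1.96 * d$se))
  else sprintf("beta=%.3f (se %.3f)", d$beta, d$se)
  for (k in seq_len(nrow(d)))
    cat(sprintf("  %s (n=%d): %s P=%.3g\n", d$stratum[k], d$n_stratum[k],
                est[k], d$p[k]))
  cat(sprintf("  interaction (1 df trend): beta=%.4f se=%.4f P=%.3g\n",
              x$interaction$beta, x$interaction$se, x$interaction$p))
  invisible(x)
}

#' 1-df genotype-by-quartile interaction trend test
#'
#' Single joint model over all strata: outcome on dosage, ordinal quartile
#' index (0-3), the covariates, and the product term dosage-by-index; the
#' Wald test on the product term is the 1-degree-of-freedom interaction
#' test. An ordinal trend parameterization is used (rather than a 3-df
#' categorical interaction) because the scientific question is monotone
#' effect modification. The P value is invariant to affine relabeling of
#' the quartile index.
#'
#' @inheritParams stratified_assoc
#' @return list with `beta`, `se`, `p` for the product term (positive `beta`
#'   means the per-allele effect strengthens with higher quartiles).
#' @export
interaction_test <- function(genotypes, phenotypes, spec, variant,
                             model = c("logistic", "linear"),
                             covariates = character(), outcome = NULL,
                             robust = "none") {
  model <- match.arg(model)
  stopifnot(inherits(spec, "quartile_spec"))
  if (is.null(outcome)) outcome <- if (model == "logistic") "status" else "log_e2"
  x <- phenotypes[[spec$variable]]
  if (mean(is.na(x)) > 0.5)
    stop("quartile variable '", spec$variable, "' missing for >50% of samples")
  q <- assign_quartiles(x, spec) - 1L  # ordinal 0-3
  if (length(unique(stats::na.omit(q))) < 2)
    stop("all samples fall in a single quartile of ", spec$variable)
  ph <- phenotypes
  ph$.qidx <- q
  df <- ph[match(genotypes$samples, ph$sample_id), , drop = FALSE]
  dat <- data.frame(.y = unname(df[[outcome]]),
                    .dosage = unname(dosage_of(genotypes, variant)),
                    .qidx = unname(df$.qidx))
  for (cv in covariates) dat[[cv]] <- df[[cv]]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  rhs <- paste(c(".dosage", ".qidx", covariates, ".dosage:.qidx"),
               collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  if (model == "logistic") {
    fit <- stats::glm(fml, data = dat, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-8, maxit = 25))
    cf <- summary(fit)$coefficients
  } else {
    fit <- stats::lm(fml, data = dat)
    cf <- summary(fit)$coefficients
    if (robust == "cluster") {
      cl <- df$cluster_id[as.integer(rownames(dat))]
      se_cl <- cluster_se(fit, cl)
      cf[, 2] <- se_cl[rownames(cf)]
    }
  }
  term <- ".dosage:.qidx"
  beta <- cf[term, 1]; se <- cf[term, 2]
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Subset a genotype matrix by sample
#' @param genotypes a [geno_matrix()].
#' @param samples character vector of sample ids to keep (order preserved).
#' @return a [geno_matrix()] restricted to those samples.
#' @export
subset_geno <- function(genotypes, samples) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  idx <- match(samples, genotypes$samples)
  if (anyNA(idx)) stop("unknown samples in subset")
  geno_matrix(genotypes$dosage[idx, , drop = FALSE], genotypes$variants, samples)
}
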