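### Per-variant association engines: per-allele (1 df) logistic trend tests
### for case-control status and linear models for log-scale hormone outcomes,
### with optional cluster-robust (sandwich) standard errors.

assoc_row <- function(variant_id, position, model, beta, se, p, n_used,
                      freq_case = NA_real_, freq_ctrl = NA_real_,
                      freq = NA_real_, robust = "none", converged = TRUE) {
  data.frame(variant_id = variant_id, position = position, model = model,
             beta = beta, se = se, p = p, n_used = n_used,
             freq_case = freq_case, freq_ctrl = freq_ctrl, freq = freq,
             robust = robust, converged = converged,
             stringsAsFactors = FALSE)
}

## assemble the per-variant complete-case model frame
model_frame <- function(genotypes, phenotypes, variant, outcome, covariates,
                        extra = NULL) {
  df <- phenotypes[match(genotypes$samples, phenotypes$sample_id), , drop = FALSE]
  dat <- data.frame(.y = unname(df[[outcome]]),
                    .dosage = unname(genotypes$dosage[, variant]))
  for (cv in covariates) {
    if (!cv %in% names(df)) stop("covariate '", cv, "' not in phenotype table")
    dat[[cv]] <- df[[cv]]
  }
  if (!is.null(extra)) dat$.lead <- extra
  dat[stats::complete.cases(dat), , drop = FALSE]
}

## covariates come first so that a dosage collinear with them (e.g. a
## perfect proxy of the conditioning lead) is the aliased, NA-flagged term
fit_formula <- function(covariates) {
  rhs <- c(covariates, ".dosage")
  stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
}

logistic_one <- function(dat, covariates) {
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fit_formula(covariates), data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 25)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  ## quasi-separation can "converge" silently: degenerate fitted
  ## probabilities mean the MLE is at infinity
  degenerate <- any(fit$fitted.values > 1 - 1e-10 | fit$fitted.values < 1e-10)
  ok <- fit$converged && !sep_warn && !degenerate &&
    ".dosage" %in% rownames(cf) && is.finite(cf[".dosage", 2])
  if (!ok) return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                       converged = FALSE, fit = fit))
  list(beta = cf[".dosage", 1], se = cf[".dosage", 2], p = cf[".dosage", 4],
       converged = TRUE, fit = fit)
}

#' Per-allele logistic trend test
#'
#' Unconditional logistic regression of case-control status on effect-allele
#' dosage (a single linear term: the per-allele, 1-degree-of-freedom trend
#' model), fit per variant on complete cases by iteratively reweighted least
#' squares (gradient tolerance 1e-8, at most 25 iterations). Wald tests are
#' reported throughout. Non-convergence or quasi-separation yields a flagged
#' `NA` row rather than an exception, so region-wide scans never abort.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes phenotype data.frame with a 0/1 `status` column (plus
#'   any covariate columns).
#' @param covariates character vector of covariate column names entered
#'   additively.
#' @param variants optional subset of variant ids to test (default: all).
#' @param outcome outcome column, default `"status"`.
#' @return data.frame with one row per variant: `variant_id`, `position`,
#'   `model`, `beta` (log-OR per effect allele), `se`, `p` (two-sided Wald),
#'   `n_used`, `freq_case`, `freq_ctrl`, `converged`. `exp(beta)` is the
#'   per-allele OR; its 95 percent CI is `exp(beta +/- 1.96 se)`.
#' @export
logistic_trend <- function(genotypes, phenotypes, covariates = character(),
                           variants = NULL, outcome = "status") {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!outcome %in% names(phenotypes)) stop("no '", outcome, "' column")
  if (is.null(variants)) variants <- genotypes$variants$id
  y_all <- phenotypes[[outcome]][match(genotypes$samples, phenotypes$sample_id)]
  yv <- unique(stats::na.omit(y_all))
  if (length(yv) < 2)
    stop("outcome '", outcome, "' has a single level (all-case or all-control input)")
  out <- vector("list", length(variants))
  for (k in seq_along(variants)) {
    v <- variants[k]
    pos <- genotypes$variants$position[match(v, genotypes$variants$id)]
    dat <- model_frame(genotypes, phenotypes, v, outcome, covariates)
    if (length(unique(dat$.y)) < 2) {
      out[[k]] <- assoc_row(v, pos, "logistic", NA, NA, NA, nrow(dat),
                            converged = FALSE)
      next
    }
    r <- logistic_one(dat, covariates)
    out[[k]] <- assoc_row(v, pos, "logistic", r$beta, r$se, r$p, nrow(dat),
                          freq_case = mean(dat$.dosage[dat$.y == 1]) / 2,
                          freq_ctrl = mean(dat$.dosage[dat$.y == 0]) / 2,
                          converged = r$converged)
  }
  res <- do.call(rbind, out)
  attr(res, "covariates") <- covariates
  res
}

## explicit clustered sandwich (X'X)^-1 (sum_g X_g' e_g e_g' X_g) (X'X)^-1
## with the G/(G-1) * (n-1)/(n-k) small-sample factor; numerically identical
## to sandwich::vcovCL(type = "HC1"), which is used as the implementation.
cluster_se <- function(fit, cluster) {
  G <- length(unique(cluster))
  if (G < 2) stop("cluster-robust errors need at least 2 clusters")
  V <- sandwich::vcovCL(fit, cluster = cluster, type = "HC1")
  sqrt(diag(V))
}

#' Linear association with a log-scale hormone outcome
#'
#' Ordinary least squares of a log-transformed hormone outcome on
#' effect-allele dosage plus covariates, per variant on complete cases.
#' `robust = "cluster"` replaces the model-based standard errors with the
#' clustered sandwich estimator over `cluster_id` groups (small-sample
#' factor `G/(G-1) * (n-1)/(n-k)`), which makes the inference valid under
#' within-family correlation such as the sister-pair structure of a
#' family-based hormone study.
#'
#' @inheritParams logistic_trend
#' @param outcome one of the log-scale hormone columns, typically `"log_e2"`
#'   or `"log_e2t"` (log of the estradiol:testosterone ratio).
#' @param robust `"none"` or `"cluster"`.
#' @return data.frame as [logistic_trend()], with `beta` the slope per
#'   effect allele on the natural-log scale and `freq` the effect-allele
#'   frequency among analyzed samples. Percent-per-allele interpretation is
#'   provided by [percent_per_allele()].
#' @export
linear_assoc <- function(genotypes, phenotypes, outcome = "log_e2",
                         covariates = character(), robust = c("none", "cluster"),
                         variants = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  robust <- match.arg(robust)
  if (!outcome %in% names(phenotypes)) stop("no '", outcome, "' column")
  if (is.null(variants)) variants <- genotypes$variants$id
  need_cl <- robust == "cluster"
  out <- vector("list", length(variants))
  for (k in seq_along(variants)) {
    v <- variants[k]
    pos <- genotypes$variants$position[match(v, genotypes$variants$id)]
    cl_all <- phenotypes$cluster_id[match(genotypes$samples, phenotypes$sample_id)]
    dat <- model_frame(genotypes, phenotypes, v, outcome, covariates)
    ## rownames of dat index into the original sample order
    cl <- cl_all[as.integer(rownames(dat))]
    if (stats::var(dat$.y) == 0) stop("constant outcome '", outcome, "'")
    fit <- stats::lm(fit_formula(covariates), data = dat)
    cf <- summary(fit)$coefficients
    if (!".dosage" %in% rownames(cf) || !is.finite(cf[".dosage", 2])) {
      ## aliased (e.g. perfect proxy of a conditioning covariate)
      out[[k]] <- assoc_row(v, pos, "linear", NA, NA, NA, nrow(dat),
                            freq = mean(dat$.dosage) / 2, converged = FALSE)
      next
    }
    beta <- cf[".dosage", 1]
    if (need_cl) {
      if (length(unique(cl)) < 2)
        stop("cluster-robust errors need at least 2 clusters")
      se <- cluster_se(fit, cl)[".dosage"]
    } else se <- cf[".dosage", 2]
    p <- 2 * stats::pnorm(-abs(beta / se))
    out[[k]] <- assoc_row(v, pos, "linear", beta, se, p, nrow(dat),
                          freq = mean(dat$.dosage) / 2, robust =
                            if (need_cl) "cluster-sandwich" else "none")
  }
  res <- do.call(rbind, out)
  attr(res, "covariates") <- covariates
  res
}

#' Case-only comparison of two case subgroups
#'
#' Per-allele logistic trend test with subgroup membership (for example
#' endometrioid versus non-endometrioid histology) as the outcome, restricted
#' to cases. Tests whether the variant's effect differs between the
#' subtypes via their allele-frequency difference.
#'
#' @inheritParams logistic_trend
#' @param subgroup name of the phenotype column holding the subgroup labels.
#' @param levels optional length-2 character vector selecting and ordering
#'   the two subgroups (second level is coded 1).
#' @return data.frame as [logistic_trend()] restricted to cases.
#' @export
case_case_test <- function(genotypes, phenotypes, subgroup,
                           covariates = character(), variants = NULL,
                           levels = NULL) {
  if (!subgroup %in% names(phenotypes)) stop("no '", subgroup, "' column")
  ph <- phenotypes[!is.na(phenotypes$status) & phenotypes$status == 1, , drop = FALSE]
  lv <- unique(stats::na.omit(ph[[subgroup]]))
  if (!is.null(levels)) lv <- levels
  if (length(lv) != 2 || any(table(ph[[subgroup]])[lv] == 0, na.rm = TRUE) ||
      !all(lv %in% ph[[subgroup]]))
    stop("subgroup '", subgroup, "' must have exactly 2 non-empty levels among cases")
  ph$.member <- ifelse(ph[[subgroup]] == lv[2], 1L,
                       ifelse(ph[[subgroup]] == lv[1], 0L, NA_integer_))
  logistic_trend(genotypes, ph, covariates, variants, outcome = ".member")
}
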