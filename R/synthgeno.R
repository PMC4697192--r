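### Synthetic regional genotype / phenotype generator.
###
### Emulates the statistical structure of a multi-study case-control scan of
### one LD-structured region with a single causal variant, an associated
### post-menopausal hormone cohort, and optional genotype-by-BMI effect
### modification -- so every downstream stage (association, meta-analysis,
### conditional fine-mapping, stratification, Mendelian randomization) can be
### exercised and tested without any individual-level consortium data.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator calls never perturb the
#' caller's RNG state (no implicit global RNG).
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive an independent child-stream seed from a master seed
#'
#' Counter-based scheme: stream `k` gets the `k`-th draw of a seeded integer
#' sequence, so each module can be driven from its own reproducible stream.
#' @param seed master integer seed.
#' @param stream positive integer stream counter.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(length(stream) == 1, stream >= 1)
  with_seed(seed, sample.int(2147483646L, stream)[stream])
}

rtnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: the regional variant grid,
#' the LD model, the causal effect sizes for disease and hormones, covariate
#' and batch structure, and the per-study case/control design. The defaults
#' are the study conditions the pipeline is validated against: four
#' case-control studies totalling 6608 cases / 37925 controls, control
#' effect-allele frequency 0.651 with per-allele disease OR 1.15, and a
#' hormone cohort of 2767 post-menopausal women with per-allele effect 0.096
#' on log estradiol (residual SD 0.64, giving slope SE near 0.018).
#'
#' @param seed mandatory integer master seed; all randomness flows from it
#'   via counter-based child streams.
#' @param n_variants number of variants on the regional grid.
#' @param region inclusive bp bounds of the region (labels only).
#' @param effect_freqs target effect-allele frequencies, length `n_variants`;
#'   default spreads frequencies over `[0.2, 0.8]` with the causal variant at
#'   0.651.
#' @param causal_index column index of the causal variant.
#' @param r2_adjacent target r-squared between adjacent variants (scalar or
#'   length `n_variants - 1`).
#' @param ld_decay_bp optional exponential decay length for LD with distance;
#'   `NULL` means no extra decay beyond the Markov chain.
#' @param n_haplotypes haplotype pool size.
#' @param log_or per-allele log odds ratio of disease for the causal variant.
#' @param studies data.frame with columns `study`, `n_case`, `n_control`;
#'   default: three GWAS sets splitting 2206/8885 plus iCOGS 4402/29040.
#' @param gxe_coef genotype-by-BMI-quartile interaction on the disease log-OR
#'   scale (added per quartile index 0-3); 0 disables effect modification.
#' @param bmi_logor,age_logor per-quartile log-OR of disease for BMI and age
#'   (the covariate main effects driving the retrospective covariate
#'   distributions).
#' @param bmi_cutpoints,age_cutpoints case-distribution quartile cutpoints.
#' @param beta_e2,beta_t per-allele effects on log estradiol and log
#'   testosterone.
#' @param sigma_e2,sigma_t residual SDs of log E2 / log T (must be > 0). The
#'   log E2 residual variance is not identified by any published quantity and
#'   is a free parameter here.
#' @param n_hormone hormone-cohort size.
#' @param covariate_effects named list of log-E2 covariate effects
#'   (`age` per year, `bmi` per kg/m2, `hrt`, `menopause` for the >5y
#'   category).
#' @param batch_sd,study_e2 SD of laboratory-batch effects and the SIBS study
#'   offset on log E2.
#' @param cluster_sd,cluster_frac SD of the shared familial (sister-pair)
#'   random effect and the fraction of SIBS women in such pairs.
#' @param or_doubling,ci_doubling external disease OR per doubling of E2 with
#'   its 95 percent CI (used when generating disease through E2).
#' @param histology optional list(`labels`, `fracs`, `logors`) simulating case
#'   subgroups with subgroup-specific per-allele log-ORs.
#'
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_variants = 25,
                       region = c(50899000, 52095000),
                       effect_freqs = NULL,
                       causal_index = NULL,
                       r2_adjacent = 0.8,
                       ld_decay_bp = NULL,
                       n_haplotypes = 10000,
                       log_or = log(1.15),
                       studies = NULL,
                       gxe_coef = 0,
                       bmi_logor = log(1.60),
                       age_logor = log(1.50),
                       bmi_cutpoints = c(24.3, 28.0, 33.2),
                       age_cutpoints = c(57, 63, 69),
                       beta_e2 = 0.096,
                       beta_t = -0.045,
                       sigma_e2 = 0.64,
                       sigma_t = 0.50,
                       n_hormone = 2767,
                       covariate_effects = list(age = -0.004, bmi = 0.04,
                                                hrt = 0.10, menopause = -0.08),
                       batch_sd = 0.15,
                       study_e2 = 0.10,
                       cluster_sd = 0.25,
                       cluster_frac = 0.2,
                       or_doubling = 2.06,
                       ci_doubling = c(1.47, 2.89),
                       histology = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory: no implicit global RNG")
  seed <- as.integer(seed)
  if (is.null(causal_index)) causal_index <- max(1L, ceiling(n_variants / 2))
  if (is.null(effect_freqs)) {
    ## a ladder of frequencies around the causal variant's 0.651: close
    ## frequencies keep high adjacent LD targets feasible (the Markov bound
    ## tightens as neighbouring frequencies separate)
    effect_freqs <- seq(0.60, 0.70, length.out = n_variants)
    effect_freqs[causal_index] <- 0.651
  }
  if (length(effect_freqs) != n_variants)
    stop("effect_freqs must have length n_variants")
  if (any(effect_freqs <= 0 | effect_freqs >= 1))
    stop("effect-allele frequencies must lie in (0, 1)")
  if (any(r2_adjacent < 0 | r2_adjacent > 1))
    stop("r2_adjacent must lie in [0, 1]")
  if (sigma_e2 <= 0 || sigma_t <= 0) stop("residual SDs must be positive")
  if (is.null(studies)) {
    studies <- data.frame(
      study     = c("GWAS1", "GWAS2", "GWAS3", "ICOGS"),
      n_case    = c(736L, 735L, 735L, 4402L),
      n_control = c(2962L, 2962L, 2961L, 29040L))
  }
  if (any(studies$n_case <= 0) || any(studies$n_control <= 0))
    stop("every study needs at least one case and one control")
  if (causal_index < 1 || causal_index > n_variants)
    stop("causal_index out of range")
  cfg <- list(seed = seed, n_variants = as.integer(n_variants), region = region,
              effect_freqs = effect_freqs, causal_index = as.integer(causal_index),
              r2_adjacent = r2_adjacent, ld_decay_bp = ld_decay_bp,
              n_haplotypes = as.integer(n_haplotypes), log_or = log_or,
              studies = studies, gxe_coef = gxe_coef,
              bmi_logor = bmi_logor, age_logor = age_logor,
              bmi_cutpoints = bmi_cutpoints, age_cutpoints = age_cutpoints,
              beta_e2 = beta_e2, beta_t = beta_t,
              sigma_e2 = sigma_e2, sigma_t = sigma_t,
              n_hormone = as.integer(n_hormone),
              covariate_effects = covariate_effects,
              batch_sd = batch_sd, study_e2 = study_e2,
              cluster_sd = cluster_sd, cluster_frac = cluster_frac,
              or_doubling = or_doubling, ci_doubling = ci_doubling,
              histology = histology)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_variants, " variants, causal #", x$causal_index,
      " (f=", round(x$effect_freqs[x$causal_index], 3),
      ", OR=", round(exp(x$log_or), 3), ")\n", sep = "")
  cat("  studies: ", paste0(x$studies$study, " ", x$studies$n_case, "/",
                            x$studies$n_control, collapse = ", "), "\n", sep = "")
  cat("  hormone arm: n=", x$n_hormone, ", beta_E2=", x$beta_e2,
      ", sigma=", x$sigma_e2, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

variant_table <- function(config) {
  pos <- round(seq(config$region[1], config$region[2],
                   length.out = config$n_variants))
  pos <- pos + seq_len(config$n_variants)  # guarantee strict increase
  data.frame(id = sprintf("var%03d", seq_len(config$n_variants)),
             position = pos, ref = "G", alt = "A",
             effect_allele = "alt", effect_freq = config$effect_freqs,
             stringsAsFactors = FALSE)
}

#' Simulate an LD-structured haplotype pool
#'
#' Binary haplotypes are generated by a first-order Markov chain along the
#' ordered variants: each variant keeps its target marginal frequency while
#' adjacent pairs attain a target correlation `r = sqrt(r2_adjacent)`,
#' optionally damped with inter-variant distance
#' (`exp(-distance / ld_decay_bp)`). Correlation between non-adjacent
#' variants decays as the product of the intervening adjacent correlations.
#' This is a deliberate simplification of coalescent LD: it is sufficient to
#' exercise r-squared filtering and conditional analysis, not to mimic real
#' haplotype block structure.
#'
#' @param config a [sim_config()].
#' @param n_hap pool size (number of haplotypes); default
#'   `config$n_haplotypes`.
#' @return integer matrix `n_hap x n_variants` of 0/1 alleles with the
#'   variant table attached as attribute `"variants"`.
#' @export
simulate_haplotypes <- function(config, n_hap = config$n_haplotypes) {
  stopifnot(inherits(config, "sim_config"))
  vt <- variant_table(config)
  m <- config$n_variants
  f <- config$effect_freqs
  r2 <- rep_len(config$r2_adjacent, max(m - 1, 1))
  r <- sqrt(r2)
  if (!is.null(config$ld_decay_bp) && m > 1) {
    d <- diff(vt$position)
    r <- r * exp(-d / config$ld_decay_bp)
  }
  with_seed(stream_seed(config$seed, 1L), {
    H <- matrix(0L, n_hap, m)
    H[, 1] <- rbinom(n_hap, 1L, f[1])
    if (m > 1) for (j in 2:m) {
      p <- f[j - 1]; q <- f[j]; rj <- r[j - 1]
      rmax <- min(sqrt(p * (1 - q) / (q * (1 - p))),
                  sqrt(q * (1 - p) / (p * (1 - q))))
      if (rj > rmax + 1e-12)
        stop("infeasible frequency/correlation pair at variants ", j - 1, "-", j,
             ": target r=", signif(rj, 3), " exceeds the bound ",
             signif(rmax, 3), " for frequencies ", p, ", ", q)
      s <- sqrt(q * (1 - q))
      p11 <- q + rj * s * sqrt((1 - p) / p)
      p01 <- q - rj * s * sqrt(p / (1 - p))
      prob <- ifelse(H[, j - 1] == 1L, p11, p01)
      H[, j] <- rbinom(n_hap, 1L, prob)
    }
    colnames(H) <- vt$id
    attr(H, "variants") <- vt
    H
  })
}

## dosage matrix from random pairing of pool haplotypes
pair_pool <- function(pool, n, seed) {
  with_seed(seed, {
    i1 <- sample.int(nrow(pool), n, replace = TRUE)
    i2 <- sample.int(nrow(pool), n, replace = TRUE)
    pool[i1, , drop = FALSE] + pool[i2, , drop = FALSE]
  })
}

## quartile machinery shared by case-control and hormone generators:
## cases are drawn uniformly over the quartile bins of their own truncated
## normal (so the case quartile cutpoints land on the configured values);
## controls are down-weighted by exp(-logor * quartile index), the
## retrospective image of a logistic model linear in quartile index.
covar_spec <- list(
  bmi = list(mean = 28.6, sd = 6.5, lo = 16, hi = 55),
  age = list(mean = 63.0, sd = 8.9, lo = 35, hi = 90))

draw_in_bins <- function(q, spec, cuts) {
  bounds <- cbind(c(spec$lo, cuts), c(cuts, spec$hi))
  x <- numeric(length(q))
  for (k in 0:3) {
    idx <- q == k
    if (any(idx))
      x[idx] <- rtnorm(sum(idx), spec$mean, spec$sd,
                       bounds[k + 1, 1], bounds[k + 1, 2])
  }
  x
}

draw_covariate <- function(n, variable, cuts, status, logor) {
  spec <- covar_spec[[variable]]
  probs <- if (status == 1) rep(0.25, 4) else {
    p <- 0.25 * exp(-logor * 0:3); p / sum(p)
  }
  q <- sample(0:3, n, replace = TRUE, prob = probs)
  list(q = q, value = draw_in_bins(q, spec, cuts))
}

## retrospective causal-dosage draw: genotype class probabilities from the
## pool frequency reweighted by exp(b * dosage), then haplotypes re-sampled
## conditional on the causal allele so regional LD is preserved.
sample_case_genotypes <- function(pool, causal, b_per_sample) {
  n <- length(b_per_sample)
  f <- mean(pool[, causal])
  if (f <= 0 || f >= 1)
    stop("causal variant is monomorphic in the haplotype pool")
  base <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  d <- integer(n)
  for (b in unique(b_per_sample)) {
    idx <- which(b_per_sample == b)
    w <- base * exp(b * 0:2)
    d[idx] <- sample(0:2, length(idx), replace = TRUE, prob = w / sum(w))
  }
  h1 <- which(pool[, causal] == 1L)
  h0 <- which(pool[, causal] == 0L)
  pick <- function(set, n) set[sample.int(length(set), n, replace = TRUE)]
  a1 <- integer(n); a2 <- integer(n)
  a1[d == 2] <- pick(h1, sum(d == 2)); a2[d == 2] <- pick(h1, sum(d == 2))
  a1[d == 1] <- pick(h1, sum(d == 1)); a2[d == 1] <- pick(h0, sum(d == 1))
  a1[d == 0] <- pick(h0, sum(d == 0)); a2[d == 0] <- pick(h0, sum(d == 0))
  pool[a1, , drop = FALSE] + pool[a2, , drop = FALSE]
}

#' Simulate a multi-study case-control dataset from a haplotype pool
#'
#' Controls are random haplotype pairs from the pool; cases are drawn
#' retrospectively, with genotype-class probabilities at the causal variant
#' reweighted by `exp(dosage * log_or)` (the rare-disease multiplicative
#' model, exact for the per-allele logistic target) and the remaining
#' variants re-sampled conditional on the causal allele so LD is preserved.
#' BMI and age are drawn per case/control stratum with the configured
#' per-quartile disease log-ORs; `gxe_coef` adds
#' `gxe_coef * BMI-quartile-index` to each case's per-allele log-OR,
#' producing genotype-by-BMI effect modification.
#'
#' @param pool haplotype pool from [simulate_haplotypes()].
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (a [geno_matrix()]) and
#'   `phenotypes` (a phenotype data.frame: `sample_id`, `status`, hormone
#'   columns set to `NA`, `age`, `bmi`, `hrt`, `menopause`, `study`, `batch`,
#'   `cluster_id`, and `histology` when subgroups are simulated).
#' @export
simulate_case_control <- function(pool, config) {
  stopifnot(inherits(config, "sim_config"))
  vt <- attr(pool, "variants")
  studies <- config$studies
  if (any(studies$n_case <= 0) || any(studies$n_control <= 0))
    stop("every study needs at least one case and one control")
  seed <- stream_seed(config$seed, 2L)
  with_seed(seed, {
    gen_list <- list(); phe_list <- list(); counter <- 0L
    for (s in seq_len(nrow(studies))) {
      n_ca <- studies$n_case[s]; n_co <- studies$n_control[s]
      lab <- studies$study[s]

      ## covariates first (the case per-allele log-OR may depend on them)
      bmi_ca <- draw_covariate(n_ca, "bmi", config$bmi_cutpoints, 1, config$bmi_logor)
      bmi_co <- draw_covariate(n_co, "bmi", config$bmi_cutpoints, 0, config$bmi_logor)
      age_ca <- draw_covariate(n_ca, "age", config$age_cutpoints, 1, config$age_logor)
      age_co <- draw_covariate(n_co, "age", config$age_cutpoints, 0, config$age_logor)

      hist_lab <- NULL
      b_case <- rep(config$log_or, n_ca)
      if (!is.null(config$histology)) {
        h <- config$histology
        hidx <- sample(seq_along(h$labels), n_ca, replace = TRUE, prob = h$fracs)
        hist_lab <- h$labels[hidx]
        b_case <- h$logors[hidx]
      }
      b_case <- b_case + config$gxe_coef * bmi_ca$q

      g_case <- sample_case_genotypes(pool, config$causal_index, b_case)
      i1 <- sample.int(nrow(pool), n_co, replace = TRUE)
      i2 <- sample.int(nrow(pool), n_co, replace = TRUE)
      g_ctrl <- pool[i1, , drop = FALSE] + pool[i2, , drop = FALSE]

      n <- n_ca + n_co
      ids <- sprintf("%s_%06d", lab, counter + seq_len(n))
      counter <- counter + n
      phe <- data.frame(
        sample_id = ids,
        status = rep(c(1L, 0L), c(n_ca, n_co)),
        log_e2 = NA_real_, log_t = NA_real_, log_e2t = NA_real_,
        age = c(age_ca$value, age_co$value),
        bmi = c(bmi_ca$value, bmi_co$value),
        hrt = rbinom(n, 1, 0.25),
        menopause = sample(c("2-5y", ">5y"), n, replace = TRUE, prob = c(0.3, 0.7)),
        study = lab, batch = lab, cluster_id = ids,
        stringsAsFactors = FALSE)
      if (!is.null(hist_lab))
        phe$histology <- c(hist_lab, rep(NA_character_, n_co))
      gen_list[[s]] <- rbind(g_case, g_ctrl)
      phe_list[[s]] <- phe
    }
    dos <- do.call(rbind, gen_list)
    phe <- do.call(rbind, phe_list)
    if (is.null(phe$histology) && !is.null(config$histology)) phe$histology <- NA
    gm <- geno_matrix(dos, vt, phe$sample_id)
    list(genotypes = gm, phenotypes = phe)
  })
}

#' Simulate hormone phenotypes for a genotyped cohort
#'
#' Log estradiol is generated as
#' `intercept + beta_e2 * dosage + covariate terms + batch + study +
#' familial-cluster effect + Gaussian noise`, and log testosterone likewise
#' with `beta_t`; `log_e2t` is their difference. A configurable fraction of
#' the SIBS-like subset is arranged in sister pairs sharing a Gaussian random
#' effect, which is what the cluster-robust standard errors downstream are
#' for.
#'
#' @param genotypes a [geno_matrix()] for the cohort (the causal column
#'   `config$causal_index` carries the genetic effect).
#' @param config a [sim_config()].
#' @return phenotype data.frame with the standard columns (`status` is `NA`:
#'   hormone cohorts are control-only).
#' @export
simulate_hormones <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"))
  if (config$sigma_e2 <= 0 || config$sigma_t <= 0)
    stop("residual SDs must be positive")
  n <- length(genotypes$samples)
  d <- genotypes$dosage[, config$causal_index]
  ce <- config$covariate_effects
  with_seed(stream_seed(config$seed, 3L), {
    age <- rtnorm(n, 63, 8.9, 48, 90)
    bmi <- rtnorm(n, 26.8, 5.5, 16, 55)
    hrt <- rbinom(n, 1, 0.25)
    meno <- sample(c("2-5y", ">5y"), n, replace = TRUE, prob = c(0.3, 0.7))
    study <- sample(c("EPIC", "SIBS"), n, replace = TRUE, prob = c(0.8, 0.2))
    batch <- sample(sprintf("lab%02d", 1:8), n, replace = TRUE)
    batch_eff <- rnorm(8, 0, config$batch_sd)
    names(batch_eff) <- sprintf("lab%02d", 1:8)

    ## sister pairs within SIBS share a cluster and a random effect
    cluster <- genotypes$samples
    sibs <- which(study == "SIBS")
    n_pair <- floor(length(sibs) * config$cluster_frac / 2)
    if (n_pair > 0) {
      paired <- matrix(sibs[seq_len(2 * n_pair)], nrow = 2)
      for (k in seq_len(n_pair))
        cluster[paired[, k]] <- sprintf("fam%05d", k)
    }
    u <- rnorm(length(unique(cluster)), 0, config$cluster_sd)
    names(u) <- unique(cluster)

    mu_e2 <- 3.0
    log_e2 <- mu_e2 + config$beta_e2 * d +
      ce$age * (age - 63) + ce$bmi * (bmi - 27) + ce$hrt * hrt +
      ce$menopause * (meno == ">5y") + batch_eff[batch] +
      config$study_e2 * (study == "SIBS") + u[cluster] +
      rnorm(n, 0, config$sigma_e2)
    log_t <- -0.2 + config$beta_t * d + 0.01 * (bmi - 27) +
      0.5 * u[cluster] + rnorm(n, 0, config$sigma_t)
    data.frame(sample_id = genotypes$samples, status = NA_integer_,
               log_e2 = as.numeric(log_e2), log_t = as.numeric(log_t),
               log_e2t = as.numeric(log_e2 - log_t),
               age = age, bmi = bmi, hrt = hrt, menopause = meno,
               study = study, batch = batch, cluster_id = cluster,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a hormone cohort (genotypes plus phenotypes)
#'
#' Convenience wrapper: draws `config$n_hormone` women as random haplotype
#' pairs from `pool` (or from Hardy-Weinberg proportions at the configured
#' frequencies when `pool` is `NULL`) and attaches hormone phenotypes.
#'
#' @inheritParams simulate_case_control
#' @return list with `genotypes` and `phenotypes`.
#' @export
simulate_hormone_cohort <- function(config, pool = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_hormone
  vt <- variant_table(config)
  if (is.null(pool)) {
    dos <- with_seed(stream_seed(config$seed, 4L), {
      sapply(config$effect_freqs, function(f) rbinom(n, 2, f))
    })
  } else {
    dos <- pair_pool(pool, n, stream_seed(config$seed, 4L))
  }
  gm <- geno_matrix(dos, vt, sprintf("H_%06d", seq_len(n)))
  list(genotypes = gm, phenotypes = simulate_hormones(gm, config))
}

#' Simulate a case-control study where disease risk acts through estradiol
#'
#' The causal chain of the Mendelian-randomization argument, made literal:
#' each woman's log E2 is generated from her causal-variant dosage
#' (`beta_e2`), and her disease risk is logistic-linear in log2(E2) with the
#' configured OR per doubling (`or_doubling`). Cases are drawn from a large
#' candidate pool with weights proportional to `exp(ln(or_doubling) *
#' log2(E2))`; controls are unweighted pool draws (rare-disease
#' approximation). Genotype affects disease only through E2, so the observed
#' per-allele OR should match the Wald-ratio prediction from the hormone arm.
#'
#' @inheritParams simulate_case_control
#' @param n_case,n_control totals (defaults: the configured study totals).
#' @return list with `genotypes` and `phenotypes` (`status` 0/1).
#' @export
simulate_disease_via_e2 <- function(pool, config,
                                    n_case = sum(config$studies$n_case),
                                    n_control = sum(config$studies$n_control)) {
  stopifnot(inherits(config, "sim_config"))
  vt <- attr(pool, "variants")
  c_e2 <- log(config$or_doubling) / log(2)
  with_seed(stream_seed(config$seed, 5L), {
    m <- max(10L * n_case, 5000L)
    i1 <- sample.int(nrow(pool), m, replace = TRUE)
    i2 <- sample.int(nrow(pool), m, replace = TRUE)
    cand <- pool[i1, , drop = FALSE] + pool[i2, , drop = FALSE]
    d <- cand[, config$causal_index]
    ln_e2 <- 3.0 + config$beta_e2 * d + rnorm(m, 0, config$sigma_e2)
    w <- exp(c_e2 * (ln_e2 - mean(ln_e2)))
    case_idx <- sample.int(m, n_case, prob = w)
    g_case <- cand[case_idx, , drop = FALSE]
    j1 <- sample.int(nrow(pool), n_control, replace = TRUE)
    j2 <- sample.int(nrow(pool), n_control, replace = TRUE)
    g_ctrl <- pool[j1, , drop = FALSE] + pool[j2, , drop = FALSE]
    n <- n_case + n_control
    ids <- sprintf("M_%06d", seq_len(n))
    gm <- geno_matrix(rbind(g_case, g_ctrl), vt, ids)
    phe <- data.frame(sample_id = ids,
                      status = rep(c(1L, 0L), c(n_case, n_control)),
                      log_e2 = NA_real_, log_t = NA_real_, log_e2t = NA_real_,
                      age = NA_real_, bmi = NA_real_, hrt = NA_integer_,
                      menopause = NA_character_, study = "MR", batch = "MR",
                      cluster_id = ids, stringsAsFactors = FALSE)
    list(genotypes = gm, phenotypes = phe)
  })
}
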