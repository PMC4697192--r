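spec_bmi <- structure(list(variable = "bmi", cutpoints = c(24.3, 28.0, 33.2),
                           labels = paste0("Q", 1:4)), class = "quartile_spec")

test_that("case quartiles are the 25/50/75 percentiles of the case values", {
  ph <- data.frame(sample_id = as.character(1:202),
                   status = c(rep(1, 101), rep(0, 101)),
                   bmi = c(0:100, rnorm(101, 40, 1)))
  sp <- case_quartiles(ph, "bmi")
  expect_equal(sp$cutpoints, c(25, 50, 75))   # controls must not contribute
  expect_error(case_quartiles(data.frame(sample_id = "a", status = 1,
                                         bmi = 20), "bmi"),
               "at least 4")
})

test_that("quartile assignment uses left-closed right-open intervals", {
  ## boundary conventions: <24.3 is Q1, 28.0 falls in Q3, 33.2 in Q4
  expect_equal(assign_quartiles(c(24.29, 24.3, 28.0, 33.19, 33.2, 10, 50),
                                spec_bmi),
               c(1L, 2L, 3L, 3L, 4L, 1L, 4L))
  ## assignment partitions all non-missing samples
  set.seed(3)
  x <- c(rnorm(500, 28, 6), NA, NA)
  q <- assign_quartiles(x, spec_bmi)
  expect_equal(sum(table(q)), 500)
  expect_true(all(q[!is.na(x)] %in% 1:4))
  expect_true(all(is.na(q[is.na(x)])))
})

test_that("stratified estimates agree with the joint model in the null case", {
  ## noiseless linear outcome, no interaction: per-stratum slopes and the
  ## joint main effect must coincide
  set.seed(31)
  n <- 800
  dos <- matrix(rbinom(n, 2, 0.5), ncol = 1)
  gm <- toy_geno(dos)
  bmi <- runif(n, 18, 45)
  ph <- data.frame(sample_id = gm$samples, status = rep(c(1, 0), n / 2),
                   bmi = bmi, log_e2 = 3 + 0.25 * dos[, 1],
                   cluster_id = gm$samples)
  st <- suppressWarnings(
    stratified_assoc(gm, ph, spec_bmi, "v01", model = "linear",
                     outcome = "log_e2"))
  expect_equal(nrow(st$strata), 4)
  expect_true(all(abs(st$strata$beta - 0.25) < 1e-6))
  expect_lt(abs(st$interaction$beta), 1e-6)

  ph_empty <- ph; ph_empty$bmi <- 20
  expect_error(suppressWarnings(
    stratified_assoc(gm, ph_empty, spec_bmi, "v01", model = "linear",
                     outcome = "log_e2")), "empty stratum Q2")
})

test_that("interaction test is calibrated under the null", {
  rejections <- logical(200)
  for (r in 1:200) {
    set.seed(4000 + r)
    n <- 400
    dos <- matrix(rbinom(n, 2, 0.5), ncol = 1)
    gm <- toy_geno(dos)
    ph <- data.frame(sample_id = gm$samples,
                     bmi = rnorm(n, 28, 6),
                     log_e2 = rnorm(n, 3 + 0.1 * dos[, 1], 0.6))
    it <- interaction_test(gm, ph, spec_bmi, "v01", model = "linear",
                           outcome = "log_e2")
    rejections[r] <- it$p < 0.05
  }
  expect_lt(mean(rejections), 0.11)   # about the nominal 5% level
  expect_gt(mean(rejections), 0.0)
})

test_that("a generated genotype-by-BMI interaction is recovered", {
  ## per-quartile increment of 0.05 on the disease log-OR scale
  betas <- ses <- numeric(10)
  for (r in 1:10) {
    cfg <- sim_config(seed = 5000 + r, n_variants = 1, effect_freqs = 0.651,
                      causal_index = 1, n_haplotypes = 6000,
                      gxe_coef = 0.05,
                      studies = data.frame(study = "ICOGS", n_case = 2858,
                                           n_control = 14098))
    sim <- simulate_case_control(simulate_haplotypes(cfg), cfg)
    sp <- case_quartiles(sim$phenotypes, "bmi")
    it <- interaction_test(sim$genotypes, sim$phenotypes, sp, "var001",
                           model = "logistic", covariates = "age")
    betas[r] <- it$beta; ses[r] <- it$se
  }
  mc_se <- sd(betas) / sqrt(length(betas))
  expect_gt(mean(betas), 0)
  expect_lt(abs(mean(betas) - 0.05), 2 * mc_se + 0.01)

  ## degenerate input: every sample in one quartile
  gm <- toy_geno(matrix(rbinom(100, 2, 0.5), ncol = 1))
  ph <- data.frame(sample_id = gm$samples, status = rbinom(100, 1, 0.3),
                   bmi = 20)
  expect_error(interaction_test(gm, ph, spec_bmi, "v01"), "single quartile")
  ph$bmi[1:60] <- NA
  expect_error(interaction_test(gm, ph, spec_bmi, "v01"), ">50%")
})

test_that("interaction P is invariant to affine relabeling of the index", {
  set.seed(41)
  n <- 600
  dos <- matrix(rbinom(n, 2, 0.5), ncol = 1)
  gm <- toy_geno(dos)
  bmi <- rnorm(n, 28, 6)
  q <- assign_quartiles(bmi, spec_bmi) - 1
  y <- rnorm(n, 3 + 0.1 * dos[, 1] + 0.03 * dos[, 1] * q, 0.5)
  ph <- data.frame(sample_id = gm$samples, bmi = bmi, log_e2 = y)
  it <- interaction_test(gm, ph, spec_bmi, "v01", model = "linear",
                         outcome = "log_e2")
  ## same model with the index affinely relabeled (5q - 7)
  fit <- lm(y ~ dos[, 1] * I(5 * q - 7))
  p_affine <- summary(fit)$coefficients[4, 4]
  ## lm uses t, interaction_test a normal approximation; compare the z
  z_affine <- summary(fit)$coefficients[4, 3]
  expect_equal(abs(it$beta / it$se), abs(z_affine), tolerance = 1e-8)
})

test_that("monotone per-stratum odds ratios emerge under effect modification", {
  cfg <- sim_config(seed = 52, n_variants = 1, effect_freqs = 0.651,
                    causal_index = 1, n_haplotypes = 6000,
                    log_or = log(1.08), gxe_coef = 0.05,
                    studies = data.frame(study = "ICOGS", n_case = 12000,
                                         n_control = 40000))
  sim <- simulate_case_control(simulate_haplotypes(cfg), cfg)
  sp <- case_quartiles(sim$phenotypes, "bmi")
  st <- stratified_assoc(sim$genotypes, sim$phenotypes, sp, "var001",
                         model = "logistic", covariates = "age")
  ors <- exp(st$strata$beta)
  expect_gt(ors[4], ors[1])             # top vs bottom quartile
  expect_gt(cor(1:4, st$strata$beta), 0)  # increasing trend
  expect_lt(st$interaction$p, 0.05)
})
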