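test_that("haplotype pool recovers target frequencies and adjacent LD", {
  cfg <- sim_config(seed = 11, n_variants = 8, n_haplotypes = 10000,
                    r2_adjacent = 0.8)
  pool <- simulate_haplotypes(cfg)
  expect_equal(dim(pool), c(10000, 8))
  expect_true(all(abs(colMeans(pool) - cfg$effect_freqs) < 0.02))
  r2 <- sapply(1:7, function(j) hap_r2(pool, j, j + 1))
  expect_true(all(abs(r2 - 0.8) < 0.05))

  ## independence case: target correlation 0
  cfg0 <- sim_config(seed = 12, n_variants = 4, n_haplotypes = 10000,
                     r2_adjacent = 0)
  pool0 <- simulate_haplotypes(cfg0)
  expect_true(all(sapply(1:3, function(j) hap_r2(pool0, j, j + 1)) < 0.05))

  ## near-perfect proxy pair
  cfg99 <- sim_config(seed = 13, n_variants = 2, n_haplotypes = 10000,
                      effect_freqs = c(0.651, 0.651), causal_index = 1,
                      r2_adjacent = 0.99)
  expect_gte(hap_r2(simulate_haplotypes(cfg99)), 0.9)
})

test_that("infeasible frequency/correlation pairs raise a parameterization error", {
  cfg <- sim_config(seed = 1, n_variants = 2, effect_freqs = c(0.05, 0.9),
                    causal_index = 1, r2_adjacent = 0.9)
  expect_error(simulate_haplotypes(cfg), "infeasible frequency/correlation")
})

test_that("retrospective case sampling matches the closed-form allele frequency", {
  ## case allele odds = OR x control allele odds under HWE:
  ## f_case = f OR / (1 - f + f OR) = 0.6821 for f = 0.651, OR = 1.15
  cfg <- sim_config(seed = 21, n_variants = 2, causal_index = 1,
                    effect_freqs = c(0.651, 0.66), n_haplotypes = 20000,
                    log_or = log(1.15),
                    studies = data.frame(study = "S", n_case = 30000,
                                         n_control = 5000))
  sim <- simulate_case_control(simulate_haplotypes(cfg), cfg)
  f <- allele_freq(sim$genotypes,
                   sim$phenotypes$sample_id[sim$phenotypes$status == 1])
  expect_equal(unname(f[1]), 0.651 * 1.15 / (1 - 0.651 + 0.651 * 1.15),
               tolerance = 0.012)
  f_ctrl <- allele_freq(sim$genotypes,
                        sim$phenotypes$sample_id[sim$phenotypes$status == 0])
  expect_equal(unname(f_ctrl[1]), mean(simulate_haplotypes(cfg)[, 1]),
               tolerance = 0.012)

  ## null model: equal frequencies when log OR = 0
  cfg0 <- sim_config(seed = 22, n_variants = 1, effect_freqs = 0.651,
                     causal_index = 1, log_or = 0, n_haplotypes = 20000,
                     studies = data.frame(study = "S", n_case = 10000,
                                          n_control = 10000))
  sim0 <- simulate_case_control(simulate_haplotypes(cfg0), cfg0)
  fc <- allele_freq(sim0$genotypes,
                    sim0$phenotypes$sample_id[sim0$phenotypes$status == 1])
  f0 <- allele_freq(sim0$genotypes,
                    sim0$phenotypes$sample_id[sim0$phenotypes$status == 0])
  expect_lt(abs(fc - f0), 0.015)
})

test_that("study bookkeeping and dosage invariants hold", {
  cfg <- sim_config(seed = 31, n_variants = 3, n_haplotypes = 2000,
                    r2_adjacent = 0.7,
                    studies = data.frame(study = paste0("S", 1:4),
                                         n_case = rep(1000L, 4),
                                         n_control = rep(5000L, 4)))
  sim <- simulate_case_control(simulate_haplotypes(cfg), cfg)
  expect_equal(sum(sim$phenotypes$status == 1), 4000)
  expect_equal(sum(sim$phenotypes$status == 0), 20000)
  expect_equal(unname(table(sim$phenotypes$study)), rep(6000L, 4),
               ignore_attr = TRUE)
  expect_true(all(sim$genotypes$dosage >= 0 & sim$genotypes$dosage <= 2))
  expect_equal(dim(sim$genotypes$dosage),
               c(nrow(sim$phenotypes), cfg$n_variants))
  expect_error(sim_config(seed = 1, studies = data.frame(
    study = "S", n_case = 0L, n_control = 10L)), "at least one case")
})

test_that("same seed gives identical output, different seeds differ", {
  a <- simulate_case_control(simulate_haplotypes(test_config(5)), test_config(5))
  b <- simulate_case_control(simulate_haplotypes(test_config(5)), test_config(5))
  c <- simulate_case_control(simulate_haplotypes(test_config(6)), test_config(6))
  expect_identical(a, b)
  expect_false(identical(a$genotypes$dosage, c$genotypes$dosage))
  ## generators must not touch the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_haplotypes(test_config(5))); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("hormone model recovers the generating slope without systematic bias", {
  ## null slope
  cfg0 <- sim_config(seed = 41, n_variants = 1, effect_freqs = 0.656,
                     causal_index = 1, beta_e2 = 0, n_hormone = 5000,
                     sigma_e2 = 0.5)
  h0 <- simulate_hormone_cohort(cfg0)
  r0 <- linear_assoc(h0$genotypes, h0$phenotypes, "log_e2",
                     c("age", "bmi", "hrt", "menopause", "batch", "study"))
  expect_lt(abs(r0$beta), 3 * r0$se)

  ## study-scale slope recovery: n = 2767, f = 0.656, beta = 0.096
  cfg1 <- sim_config(seed = 42, n_variants = 1, effect_freqs = 0.656,
                     causal_index = 1)
  h1 <- simulate_hormone_cohort(cfg1)
  r1 <- linear_assoc(h1$genotypes, h1$phenotypes, "log_e2",
                     c("age", "bmi", "hrt", "menopause", "batch", "study"))
  expect_lt(abs(r1$beta - 0.096), 3 * r1$se)
  expect_lt(abs(r1$se - 0.018), 0.006)  # residual SD tuned for SE near 0.018

  ## no systematic bias over 200 replicates at the study's sample size
  ## (Monte-Carlo SE criterion)
  betas <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = 1000 + s, n_variants = 1, effect_freqs = 0.656,
                      causal_index = 1)
    h <- simulate_hormone_cohort(cfg)
    linear_assoc(h$genotypes, h$phenotypes, "log_e2",
                 c("age", "bmi", "hrt", "menopause", "batch", "study"))$beta
  }, numeric(1))
  mc_se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - 0.096), 2 * mc_se + 1e-12)

  cfg_bad <- cfg1; cfg_bad$sigma_e2 <- -1
  expect_error(simulate_hormones(h1$genotypes, cfg_bad), "positive")
})

test_that("family clusters share a random effect that inflates robust SEs", {
  cfg <- sim_config(seed = 51, n_variants = 1, effect_freqs = 0.656,
                    causal_index = 1, n_hormone = 1500, cluster_frac = 0.9,
                    cluster_sd = 0.6)
  h <- simulate_hormone_cohort(cfg)
  ph <- h$phenotypes
  expect_true(any(duplicated(ph$cluster_id)))
  ## sister pairs share a random effect: residuals of paired members are
  ## positively correlated
  res <- residuals(lm(log_e2 ~ h$genotypes$dosage[, 1], data = ph))
  pairs <- split(res, ph$cluster_id)
  pairs <- do.call(rbind, pairs[lengths(pairs) == 2])
  expect_gt(nrow(pairs), 50)
  expect_gt(cor(pairs[, 1], pairs[, 2]), 0.2)
})
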