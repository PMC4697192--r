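test_that("logistic trend equals the grid-search MLE on genotype-count tables", {
  ## worked example: cases (10,20,10), controls (20,20,10)
  fx <- counts_fixture(c(10, 20, 10), c(20, 20, 10))
  r <- logistic_trend(fx$genotypes, fx$phenotypes)
  expect_lt(abs(r$beta - grid_mle_logor(c(10, 20, 10), c(20, 20, 10))), 1e-6)
  expect_equal(r$n_used, 90)
  expect_equal(r$freq_case, (20 + 2 * 10) / (2 * 40))

  ## property: MLE matches the oracle on random 2x3 tables with nonzero cells
  set.seed(1234)
  for (i in 1:100) {
    ncase <- sample(3:40, 3, replace = TRUE)
    nctrl <- sample(3:40, 3, replace = TRUE)
    fx <- counts_fixture(ncase, nctrl)
    r <- logistic_trend(fx$genotypes, fx$phenotypes)
    expect_lt(abs(r$beta - grid_mle_logor(ncase, nctrl)), 1e-6,
              label = paste("table", i, "deviation"))
  }
})

test_that("null symmetry: identical genotype distributions give OR 1", {
  fx <- counts_fixture(c(15, 30, 15), c(15, 30, 15))
  r <- logistic_trend(fx$genotypes, fx$phenotypes)
  expect_equal(exp(r$beta), 1, tolerance = 1e-6)
  expect_equal(r$freq_case, r$freq_ctrl)
})

test_that("logistic trend flags separation instead of aborting a scan", {
  ## perfectly separated variant: all carriers are cases
  dos <- cbind(c(2, 2, 2, 0, 0, 0), c(1, 0, 1, 1, 0, 1))
  gm <- toy_geno(dos)
  ph <- data.frame(sample_id = gm$samples, status = c(1, 1, 1, 0, 0, 0))
  r <- logistic_trend(gm, ph)
  expect_false(r$converged[1])
  expect_true(is.na(r$beta[1]))
  expect_true(r$converged[2])
  expect_error(logistic_trend(gm, transform(ph, status = 1)), "single level")
})

test_that("allele frequency counts dosages over non-missing samples", {
  gm <- toy_geno(cbind(c(0, 1, 2), c(2, 2, 1)))
  expect_equal(unname(allele_freq(gm)), c(0.5, 5 / 6))
  gm2 <- toy_geno(cbind(c(2, 2, 1, 1), c(2, NA, 0, NA)))
  expect_equal(unname(allele_freq(gm2)), c(0.75, 0.5))
  gm3 <- toy_geno(cbind(c(1, 1), c(NA, NA)))
  expect_warning(f <- allele_freq(gm3), "all dosages missing")
  expect_true(is.na(f[2]))
})

test_that("cluster-sandwich SEs equal the explicit matrix oracle", {
  ## 6-sample toy dataset with 3 clusters of size 2
  set.seed(7)
  dos <- matrix(rbinom(6, 2, 0.5), ncol = 1)
  gm <- toy_geno(dos)
  ph <- data.frame(sample_id = gm$samples, status = NA_integer_,
                   log_e2 = rnorm(6, 3 + 0.3 * dos[, 1], 0.5),
                   cluster_id = rep(c("f1", "f2", "f3"), each = 2))
  r <- linear_assoc(gm, ph, "log_e2", robust = "cluster")
  fit <- lm(ph$log_e2 ~ dos[, 1])
  expect_equal(r$se, unname(hand_cluster_se(fit, ph$cluster_id)[2]),
               tolerance = 1e-10)

  ## all singleton clusters reduce to HC1 heteroskedasticity-robust SEs
  ph1 <- ph; ph1$cluster_id <- ph1$sample_id
  r1 <- linear_assoc(gm, ph1, "log_e2", robust = "cluster")
  expect_equal(r1$se, unname(sqrt(diag(sandwich::vcovHC(fit, type = "HC1")))[2]),
               tolerance = 1e-10)

  ## duplicating samples into clusters of two inflates the clustered SE
  gm2 <- toy_geno(dos[rep(1:6, each = 2), , drop = FALSE])
  ph2 <- ph[rep(1:6, each = 2), ]
  ph2$sample_id <- gm2$samples
  ph2$cluster_id <- rep(sprintf("c%d", 1:6), each = 2)
  ph2s <- ph2; ph2s$cluster_id <- ph2s$sample_id
  r_pair <- linear_assoc(gm2, ph2, "log_e2", robust = "cluster")
  r_split <- linear_assoc(gm2, ph2s, "log_e2", robust = "cluster")
  expect_gt(r_pair$se, r_split$se)

  expect_error(linear_assoc(gm, transform(ph, cluster_id = "one"),
                            "log_e2", robust = "cluster"), "at least 2 clusters")
  expect_error(linear_assoc(gm, transform(ph, log_e2 = 1), "log_e2"),
               "constant outcome")
})

test_that("noiseless linear fit recovers the slope exactly", {
  dos <- matrix(c(0, 1, 2, 0, 1, 2, 1, 2, 0, 1), ncol = 1)
  gm <- toy_geno(dos)
  ph <- data.frame(sample_id = gm$samples, log_e2 = 2.5 + 0.37 * dos[, 1])
  r <- suppressWarnings(linear_assoc(gm, ph, "log_e2"))  # perfect-fit warning
  expect_equal(r$beta, 0.37, tolerance = 1e-10)
  expect_lt(r$p, 1e-12)
})

test_that("an orthogonal covariate leaves the estimate unchanged", {
  set.seed(11)
  dos <- matrix(rbinom(400, 2, 0.5), ncol = 1)
  gm <- toy_geno(dos)
  z <- rnorm(400)
  z <- residuals(lm(z ~ dos[, 1]))          # exactly orthogonal to dosage
  ph <- data.frame(sample_id = gm$samples,
                   log_e2 = rnorm(400, 3 + 0.2 * dos[, 1], 0.4), z = z)
  r0 <- linear_assoc(gm, ph, "log_e2")
  r1 <- linear_assoc(gm, ph, "log_e2", covariates = "z")
  expect_lt(abs(r0$beta - r1$beta), 1e-8)
})

test_that("swapping the effect allele negates beta and reflects the frequency", {
  set.seed(13)
  fx <- counts_fixture(c(12, 25, 13), c(30, 22, 9))
  r <- logistic_trend(fx$genotypes, fx$phenotypes)
  swapped <- fx$genotypes
  swapped$dosage <- 2 - swapped$dosage
  r2 <- logistic_trend(swapped, fx$phenotypes)
  expect_equal(r2$beta, -r$beta, tolerance = 1e-8)
  expect_equal(r2$freq_case, 1 - r$freq_case, tolerance = 1e-12)
  expect_equal(r2$se, r$se, tolerance = 1e-8)
})

test_that("case-case comparison centres on the ratio of subgroup odds ratios", {
  ## subgroups simulated against common controls with ORs 1.16 and 1.08:
  ## expected case-case per-allele OR (allele-level odds ratio) = 1.16/1.08
  cfg <- sim_config(seed = 61, n_variants = 1, effect_freqs = 0.651,
                    causal_index = 1, n_haplotypes = 20000,
                    studies = data.frame(study = "S", n_case = 30000,
                                         n_control = 1000),
                    histology = list(labels = c("endo", "non_endo"),
                                     fracs = c(0.5, 0.5),
                                     logors = log(c(1.16, 1.08))))
  sim <- simulate_case_control(simulate_haplotypes(cfg), cfg)
  r <- case_case_test(sim$genotypes, sim$phenotypes, "histology",
                      levels = c("non_endo", "endo"))
  expect_equal(exp(r$beta), 1.16 / 1.08, tolerance = 0.035)

  ## identical subgroup distributions give OR 1
  ph <- sim$phenotypes
  ph$histology[ph$status == 1] <- rep(c("endo", "non_endo"),
                                      length.out = sum(ph$status == 1))
  ## relabelled at random w.r.t. genotype: large-sample OR near 1
  r0 <- case_case_test(sim$genotypes, ph, "histology")
  expect_equal(exp(r0$beta), 1, tolerance = 0.05)

  ph_bad <- sim$phenotypes
  ph_bad$histology[ph_bad$status == 1] <- "endo"
  expect_error(case_case_test(sim$genotypes, ph_bad, "histology"),
               "2 non-empty levels")
})
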