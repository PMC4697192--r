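## Independent oracles and small fixture builders used across the suite.
## Each oracle is a direct evaluation of the defining formula, kept separate
## from the implementation paths it checks.

## Logistic per-allele MLE by direct likelihood maximization over an
## (intercept, beta) grid with iterative refinement. `ncase`/`nctrl` are
## counts by genotype class 0/1/2.
grid_mle_logor <- function(ncase, nctrl, iters = 60) {
  d <- 0:2
  centre <- c(0, 0); span <- 6
  for (it in seq_len(iters)) {
    a <- seq(centre[1] - span, centre[1] + span, length.out = 21)
    b <- seq(centre[2] - span, centre[2] + span, length.out = 21)
    g <- expand.grid(a = a, b = b)
    eta <- outer(g$a, rep(1, 3)) + outer(g$b, d)
    ll <- eta %*% ncase - log1p(exp(eta)) %*% (ncase + nctrl)
    centre <- unlist(g[which.max(ll), ])
    span <- span * 0.5
  }
  unname(centre[2])
}

## Explicit clustered sandwich: (X'X)^-1 (sum_g X_g' e_g e_g' X_g) (X'X)^-1
## with the G/(G-1) * (n-1)/(n-k) factor; returns SEs in coefficient order.
hand_cluster_se <- function(fit, cluster) {
  X <- model.matrix(fit)
  e <- residuals(fit)
  n <- nrow(X); k <- ncol(X); G <- length(unique(cluster))
  meat <- matrix(0, k, k)
  for (g in unique(cluster)) {
    sg <- t(X[cluster == g, , drop = FALSE]) %*% e[cluster == g]
    meat <- meat + sg %*% t(sg)
  }
  bread <- solve(crossprod(X))
  V <- (G / (G - 1)) * ((n - 1) / (n - k)) * bread %*% meat %*% bread
  sqrt(diag(V))
}

## Textbook haplotype-frequency LD: r2 = D^2 / (pA(1-pA) pB(1-pB)) with
## D = pAB - pA pB, computed from a binary haplotype pool.
hap_r2 <- function(pool, a = 1, b = 2) {
  pa <- mean(pool[, a]); pb <- mean(pool[, b])
  pab <- mean(pool[, a] == 1 & pool[, b] == 1)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

## Build a geno_matrix from a plain dosage matrix.
toy_geno <- function(dosage, ids = NULL, positions = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(ids)) ids <- sprintf("v%02d", seq_len(m))
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  vt <- data.frame(id = ids, position = positions, ref = "G", alt = "A",
                   effect_allele = "alt",
                   effect_freq = colMeans(dosage, na.rm = TRUE) / 2,
                   stringsAsFactors = FALSE)
  geno_matrix(dosage, vt, sprintf("s%04d", seq_len(nrow(dosage))))
}

## Case-control fixture from genotype-class counts (cases, controls).
counts_fixture <- function(ncase, nctrl) {
  dos <- c(rep(0:2, ncase), rep(0:2, nctrl))
  status <- rep(c(1L, 0L), c(sum(ncase), sum(nctrl)))
  gm <- toy_geno(matrix(dos, ncol = 1))
  ph <- data.frame(sample_id = gm$samples, status = status,
                   stringsAsFactors = FALSE)
  list(genotypes = gm, phenotypes = ph)
}

## Small default-scale config for fast pipeline tests.
test_config <- function(seed, ...) {
  sim_config(seed = seed, n_variants = 10, n_haplotypes = 4000,
             studies = data.frame(study = c("A", "B", "C", "D"),
                                  n_case = c(150, 150, 150, 600),
                                  n_control = c(600, 600, 600, 2000)),
             n_hormone = 800, ...)
}
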