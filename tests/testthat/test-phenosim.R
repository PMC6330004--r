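# Phenotype simulators and the bias/coverage audit

test_that("polygenic betas give each SNP its variance share", {
  expect_identical(polygenic_betas(rep(0.3, 10), per_snp_r2 = 0), rep(0, 10))
  # direct evaluation of the stated formula at maf 0.5, 200 SNPs
  b <- polygenic_betas(rep(0.5, 200), per_snp_r2 = 1.5e-3, noise_sd = 1)
  expect_equal(b[1], sqrt(1.5e-3 * (1 / 0.7) / 0.5), tolerance = 1e-12)
  expect_equal(b[1], 0.0655, tolerance = 1e-3)
  expect_error(polygenic_betas(rep(0.5, 200), per_snp_r2 = 0.006), "< 1")
})

test_that("the polygenic model attains its total R^2 of 0.3", {
  n <- 50000
  G <- generate_genotypes(n, snp_panel(200, maf_range = c(0.4, 0.5), seed = 2),
                          seed = 3)
  spec <- polygenic_spec(G$snps$snp_id)
  rep1 <- simulate_polygenic(G, spec, seed = 4)
  X <- cbind(1, G$values)
  storage.mode(X) <- "double"
  fit <- lm.fit(X, rep1$y)
  r2 <- 1 - sum(fit$residuals^2) / sum((rep1$y - mean(rep1$y))^2)
  expect_lt(abs(r2 - 0.30), 0.015)
})

test_that("per-SNP variance shares match the target", {
  n <- 50000
  G <- generate_genotypes(n, snp_panel(50, maf_range = c(0.4, 0.5), seed = 12),
                          seed = 13)
  spec <- polygenic_spec(G$snps$snp_id, per_snp_r2 = 1.5e-3)
  rep1 <- simulate_polygenic(G, spec, seed = 14)
  # squared marginal correlation of each SNP with y (SNPs are independent
  # here, so the semi-partial and marginal correlations coincide)
  r2s <- apply(G$values, 2, function(g) cor(g, rep1$y)^2)
  expect_lt(abs(mean(r2s) - 1.5e-3), 4e-4)
})

test_that("simulators are pure functions of (G, spec, seed)", {
  pn <- small_panel(n = 300, m = 6, seed = 5)
  spec <- effect_spec(pn$G$snps$snp_id[1:2], level = "strong")
  a <- simulate_interaction(pn$G, spec, seed = 8)
  b <- simulate_interaction(pn$G, spec, seed = 8)
  d <- simulate_interaction(pn$G, spec, seed = 9)
  expect_identical(a$y, b$y)
  expect_false(identical(a$y, d$y))
})

test_that("degenerate specs reduce to the null model", {
  pn <- small_panel(n = 5000, m = 4, seed = 6)
  zero <- effect_spec(pn$G$snps$snp_id[1:2],
                      betas = list(main = c(0, 0), pair = 0))
  ri <- simulate_interaction(pn$G, zero, seed = 17)
  rn <- simulate_null(pn$G, seed = 17)
  expect_identical(ri$y, rn$y)
  ks <- ks.test(rn$y, pnorm)
  expect_gt(ks$p.value, 0.001)
})

test_that("unknown presets and SNPs are rejected", {
  pn <- small_panel(n = 50, m = 4, seed = 7)
  expect_error(effect_spec(pn$G$snps$snp_id[1:2], level = "huge"), "strong")
  spec <- effect_spec(c("nope1", "nope2"), level = "strong")
  expect_error(simulate_interaction(pn$G, spec, seed = 1), "nope1")
})

test_that("OLS on the true model recovers every preset's coefficients", {
  n <- 1500
  G <- generate_genotypes(n, snp_panel(3, maf_range = c(0.4, 0.5), seed = 8),
                          seed = 9)
  presets <- list(c(2, "weak"), c(2, "intermediate"), c(2, "strong"),
                  c(3, "pure"), c(3, "strong"), c(3, "weak"))
  for (ps in presets) {
    k <- as.integer(ps[1])
    spec <- effect_spec(G$snps$snp_id[seq_len(k)], level = ps[2])
    Xs <- cbind(1, epistree:::true_model_design(G, spec))
    bt <- epistree:::true_model_betas(G, spec)
    n_reps <- 300
    est <- matrix(0, n_reps, length(bt))
    for (r in seq_len(n_reps)) {
      y <- simulate_interaction(G, spec, seed = derive_seed(100, r))$y
      est[r, ] <- qr.coef(qr(Xs), y)[-1]
    }
    bias <- colMeans(est) - bt
    mcse <- apply(est, 2, sd) / sqrt(n_reps)
    expect_true(all(abs(bias) < 3 * mcse),
                info = sprintf("preset %s-%s", ps[1], ps[2]))
  }
})

test_that("the pure 3-SNP interaction is overwhelmingly detectable by OLS", {
  G <- generate_genotypes(5000, snp_panel(3, maf_range = c(0.4, 0.5), seed = 10),
                          seed = 11)
  spec <- effect_spec(G$snps$snp_id, level = "pure")
  Xs <- cbind(1, epistree:::true_model_design(G, spec))
  qx <- qr(Xs)
  R <- chol2inv(qr.R(qx))
  hits <- 0L
  n_reps <- 200
  for (r in seq_len(n_reps)) {
    y <- simulate_interaction(G, spec, seed = derive_seed(200, r))$y
    beta <- qr.coef(qx, y)
    res <- y - Xs %*% beta
    se7 <- sqrt(R[8, 8] * sum(res^2) / (nrow(Xs) - ncol(Xs)))
    p <- 2 * pt(abs(beta[8] / se7), nrow(Xs) - ncol(Xs), lower.tail = FALSE)
    hits <- hits + (p < 1e-6)
  }
  expect_gt(hits / n_reps, 0.95)
})

test_that("combined phenotypes collapse to their components", {
  n <- 2000
  G <- generate_genotypes(n, snp_panel(30, maf_range = c(0.35, 0.5), seed = 12),
                          seed = 13)
  ids <- G$snps$snp_id
  pspec <- polygenic_spec(ids[1:20], per_snp_r2 = 1e-3)
  zero_i <- effect_spec(ids[21:22], betas = list(main = c(0, 0), pair = 0))
  expect_identical(simulate_combined(G, pspec, zero_i, seed = 3)$y,
                   simulate_polygenic(G, pspec, seed = 3)$y)
  empty_p <- polygenic_spec(character(), per_snp_r2 = 1e-3)
  ispec <- effect_spec(ids[21:22], level = "strong")
  expect_identical(simulate_combined(G, empty_p, ispec, seed = 4)$y,
                   simulate_interaction(G, ispec, seed = 4)$y)
  overlap <- effect_spec(ids[c(1, 21)], level = "strong")
  expect_error(simulate_combined(G, pspec, overlap, seed = 5), "disjoint")
})

test_that("variance bookkeeping matches the analytic HWE decomposition", {
  n <- 50000
  G <- generate_genotypes(n, snp_panel(202, maf_range = c(0.4, 0.5), seed = 14),
                          seed = 15)
  ids <- G$snps$snp_id
  pspec <- polygenic_spec(ids[1:200])
  ispec <- effect_spec(ids[201:202], level = "strong")
  rep1 <- simulate_combined(G, pspec, ispec, seed = 16)
  # analytic variance from HWE moments at the observed MAFs
  maf <- colMeans(G$values) / 2
  vg <- function(q) 2 * q * (1 - q)
  m2 <- function(q) vg(q) + (2 * q)^2        # E[g^2]
  q1 <- maf[201]; q2 <- maf[202]
  b <- c(ispec$main, ispec$pair)
  # var(b1 g1 + b2 g2 + b3 g1 g2) for independent g1, g2
  var_prod <- m2(q1) * m2(q2) - (2 * q1)^2 * (2 * q2)^2
  cov_g1_prod <- 2 * q2 * vg(q1)             # cov(g1, g1 g2) = E[g2] var(g1)
  cov_g2_prod <- 2 * q1 * vg(q2)
  var_int <- b[1]^2 * vg(q1) + b[2]^2 * vg(q2) + b[3]^2 * var_prod +
    2 * b[1] * b[3] * cov_g1_prod + 2 * b[2] * b[3] * cov_g2_prod
  betas <- polygenic_betas(maf[1:200])
  var_poly <- sum(betas^2 * vg(maf[1:200]))
  analytic <- var_poly + var_int + 1
  expect_lt(abs(var(rep1$y) - analytic) / analytic, 0.02)
})

test_that("the null simulator is a clean standard normal", {
  pn <- small_panel(n = 5000, m = 5, seed = 17)
  r <- simulate_null(pn$G, seed = 18)
  expect_true(all(lengths(r$truth[c("interacting", "polygenic")]) == 0))
  expect_lt(abs(mean(r$y)), 3 / sqrt(5000))
  expect_lt(abs(var(r$y) - 1), 0.06)
})

test_that("F-test p-values are uniform under the null", {
  n <- 300
  G <- generate_genotypes(n, snp_panel(30, maf_range = c(0.2, 0.5), seed = 19),
                          seed = 20)
  X <- cbind(1, G$values); storage.mode(X) <- "double"
  qx <- qr(X)
  pvals <- vapply(1:300, function(r) {
    y <- simulate_null(G, derive_seed(300, r))$y
    rss <- sum(qr.resid(qx, y)^2)
    tss <- sum((y - mean(y))^2)
    fstat <- ((tss - rss) / 30) / (rss / (n - 31))
    pf(fstat, 30, n - 31, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(ks.test(pvals, punif)$p.value, 0.001)
})

test_that("the main-effect control carries no interaction", {
  n <- 1500
  G <- generate_genotypes(n, snp_panel(2, maf_range = c(0.4, 0.5), seed = 21),
                          seed = 22)
  ids <- G$snps$snp_id
  g <- G$values; storage.mode(g) <- "double"
  X <- cbind(1, g[, 1], g[, 2], g[, 1] * g[, 2])
  qx <- qr(X)
  n_reps <- 300
  est <- matrix(0, n_reps, 3)
  for (r in seq_len(n_reps)) {
    rep1 <- simulate_main_effect(G, ids, seed = derive_seed(400, r))
    est[r, ] <- qr.coef(qx, rep1$y)[2:4]
  }
  bias <- colMeans(est) - c(0.2, 0.2, 0)
  mcse <- apply(est, 2, sd) / sqrt(n_reps)
  expect_true(all(abs(bias) < 3 * mcse))     # post-hoc interaction centred on 0
  r1 <- simulate_main_effect(G, ids, seed = 7)
  r2 <- simulate_main_effect(G, ids, seed = 7)
  expect_identical(r1$y, r2$y)
  expect_identical(r1$truth$main_effect, ids)
  expect_length(r1$truth$interacting, 0)
})

test_that("the fidelity audit recovers coefficients exactly as noise vanishes", {
  G <- generate_genotypes(400, snp_panel(2, maf_range = c(0.4, 0.5), seed = 23),
                          seed = 24)
  spec <- effect_spec(G$snps$snp_id, level = "strong", noise_sd = 1e-6)
  reps <- lapply(1:100, function(r) simulate_interaction(G, spec, derive_seed(500, r)))
  fr <- assess_fidelity(reps, G, spec)
  expect_lt(abs(fr$bias), 1e-6)            # estimates collapse onto the truth
  # coverage of the t interval is scale-free (the CI shrinks with the noise),
  # so it stays at its nominal level rather than tending to 1
  expect_lt(abs(fr$coverage - 0.95), 0.07)
})

test_that("null-model coverage matches exact OLS theory", {
  G <- generate_genotypes(500, snp_panel(2, seed = 25), seed = 26)
  reps <- lapply(1:400, function(r) simulate_null(G, derive_seed(600, r)))
  fr <- assess_fidelity(reps, G, NULL)
  expect_lt(abs(fr$coverage - 0.95), 0.035)
})

test_that("a singular generating design is rejected", {
  g <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L, 0L, 2L)
  G <- manual_genotypes(list(g, g))   # duplicated SNP -> collinear design
  spec <- effect_spec(G$snps$snp_id, level = "strong")
  reps <- lapply(1:3, function(r) simulate_interaction(G, spec, r))
  expect_error(assess_fidelity(reps, G, spec), "singular")
})
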