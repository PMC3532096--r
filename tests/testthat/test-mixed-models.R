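test_that("REML recovers the simulated variance ratio and beats a grid search", {
  fx <- cached_fixture("gblup_oracle")   # n = 50, m = 200, h2 = 0.5
  g <- fx$g
  p <- colMeans(g$calls) / 2
  G <- grm_vanraden(g, p)
  vc <- reml_single_kernel(fx$y, G)
  # grid-search oracle: the optimizer must not be beaten anywhere on a
  # 100-point grid of the same objective
  prof <- reml_profile(fx$y, G, ratios = seq(0.001, 0.995, length.out = 100))
  expect_gte(vc$loglik + 1e-6, max(prof$loglik))
  expect_true(vc$ratio >= 0 && vc$ratio <= 1)
  expect_gte(vc$sigma2_g, 0)
  expect_gte(vc$sigma2_e, 0)

  expect_error(reml_single_kernel(fx$y, -G$matrix), "positive semidefinite")
  expect_warning(reml_single_kernel(fx$y, diag(50)), "identifiable")
})

test_that("REML ratio recovery at n = 500 brackets the truth", {
  g <- hwe_genotypes(500, 800, seed = 21)
  p <- colMeans(g$calls) / 2
  G <- grm_vanraden(g, p)
  gval <- withr::with_seed(22, {
    alpha <- rnorm(800, 0, 1)
    as.numeric(scale(sweep(g$calls, 2, 2 * p) %*% alpha))
  })
  y <- gval + withr::with_seed(23, rnorm(500))  # sigma2_g = sigma2_e = 1
  vc <- reml_single_kernel(y, G)
  expect_gt(vc$ratio, 0.4)
  expect_lt(vc$ratio, 0.6)

  y0 <- withr::with_seed(24, rnorm(500))        # pure noise
  vc0 <- reml_single_kernel(y0, G)
  expect_lt(vc0$ratio, 0.1)
})

test_that("GBLUP solves Henderson's equations (dense oracle) and its limits", {
  fx <- cached_fixture("gblup_oracle")
  g <- fx$g; y <- fx$y; n <- n_animals(g)
  p <- colMeans(g$calls) / 2
  G <- grm_vanraden(g, p)
  vc <- reml_single_kernel(y, G)
  w <- withr::with_seed(31, runif(n, 0.5, 2))
  fit <- gblup_fit(y, G, vc = vc, weights = w)

  X <- matrix(1, n, 1)
  lam <- vc$sigma2_e / vc$sigma2_g
  Ginv <- solve(G$matrix + diag(1e-8, n))
  C <- rbind(cbind(crossprod(X, X * w), t(X * w)),
             cbind(X * w, diag(w) + lam * Ginv))
  sol <- solve(C, c(crossprod(X, y * w), y * w))
  expect_lt(max(abs(c(fit$beta, fit$g_hat) - sol)), 1e-8)

  # equal weights == unweighted
  f1 <- gblup_fit(y, G, vc = vc)
  f2 <- gblup_fit(y, G, vc = vc, weights = rep(1, n))
  expect_equal(f1$g_hat, f2$g_hat)
  expect_equal(f1$beta, f2$beta)

  # shrinkage limit: sigma2_g -> 0 gives g = 0 and beta -> WLS
  vc0 <- structure(list(sigma2_g = 0, sigma2_e = vc$sigma2_e, ratio = 0,
                        n = n), class = "variance_components")
  f0 <- gblup_fit(y, G, vc = vc0, weights = w)
  expect_equal(f0$g_hat, rep(0, n))
  expect_equal(f0$beta, sum(w * y) / sum(w))
})

test_that("GBLUP backsolve equals ridge SNP-BLUP and handles the null fit", {
  fx <- cached_fixture("gblup_oracle")
  g <- fx$g; y <- fx$y
  n <- n_animals(g); m <- n_loci(g)
  p <- colMeans(g$calls) / 2
  G <- grm_vanraden(g, p)
  vc <- reml_single_kernel(y, G)
  fit <- gblup_fit(y, G, vc = vc)
  scan <- backsolve_snp_effects(fit, g)

  # oracle: joint (beta, alpha) ridge solve of the SNP model
  Z <- sweep(g$calls, 2, 2 * p)
  lambda <- vc$sigma2_e * 2 * sum(p * (1 - p)) / vc$sigma2_g
  X <- matrix(1, n, 1)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lambda, m)))
  alpha <- solve(C, c(crossprod(X, y), crossprod(Z, y)))[-1]
  expect_lt(max(abs(scan$ase - alpha)), 1e-6)
  expect_true(all(scan$var_2pqa2 >= 0))
  expect_true(all(is.na(scan$p_value)))

  # g_hat = 0 => all ASEs zero
  fit0 <- fit; fit0$g_hat <- rep(0, n)
  expect_equal(backsolve_snp_effects(fit0, g)$ase, rep(0, m))
  expect_error(backsolve_snp_effects(fit, subset_genotypes(g, loci = 1:10)),
               "locus mismatch")
})

test_that("a planted large-effect locus lands in the top 1% of 2pq a^2", {
  fx <- cached_fixture("selected_sweep")
  g <- fx$g
  p <- base_allele_freqs(g, earliest_cohort(g, 60))
  G <- grm_vanraden(g, p)
  fit <- gblup_fit(g$birth_date, G)
  scan <- backsolve_snp_effects(fit, g)
  qtl_rank <- scan$rank[scan$snp == fx$qtl_snp]
  expect_lte(qtl_rank, ceiling(0.01 * n_loci(g)))
})

test_that("EMMAX with K = I reduces to OLS and p-values resist affine rescaling", {
  g <- hwe_genotypes(60, 80, seed = 41)
  y <- withr::with_seed(42, rnorm(60) + 0.3 * g$calls[, 5])
  K <- diag(60)
  es <- suppressWarnings(emmax_scan(y, K, g))
  pols <- vapply(seq_len(80), function(j)
    summary(lm(y ~ g$calls[, j]))$coefficients[2, 4], 0)
  expect_lt(max(abs(es$p_value - pols)), 1e-10)

  es2 <- suppressWarnings(emmax_scan(3.7 * y + 11, K, g))
  expect_equal(es2$p_value, es$p_value, tolerance = 1e-8)
})

test_that("EMMAX flags collinear SNPs instead of testing them", {
  g <- hwe_genotypes(40, 10, seed = 43)
  g$calls[, 1] <- 2
  y <- withr::with_seed(44, rnorm(40))
  expect_warning(es <- emmax_scan(y, diag(40), g), "collinear")
  expect_equal(es$ase[es$snp == "snp1"], 0)
  expect_equal(es$p_value[es$snp == "snp1"], 1)
})

test_that("GBLUP and EMMAX ASE ranks agree on selected data", {
  fx <- cached_fixture("selected_sweep")
  g <- fx$g
  p <- base_allele_freqs(g, earliest_cohort(g, 60))
  G <- grm_vanraden(g, p)
  scan_g <- backsolve_snp_effects(gblup_fit(g$birth_date, G), g)
  K <- balding_nichols_kinship(g)
  scan_e <- emmax_scan(g$birth_date, K, g)
  expect_gt(cor(scan_g$ase, scan_e$ase, method = "spearman"), 0.8)
})

test_that("permuting the response destroys EMMAX associations", {
  fx <- cached_fixture("neutral_null")
  g <- subset_genotypes(fx$g, loci = seq(1, 1000, by = 5))  # 200 SNPs
  K <- balding_nichols_kinship(g)
  qmin <- withr::with_seed(45, {
    vapply(1:24, function(i) {
      es <- emmax_scan(sample(g$birth_date), K, g)
      min(es$q_value)
    }, 0)
  })
  # under the global null, P(min BH q <= alpha) <= alpha (with equality for
  # independent tests); allow 1.5x that bound at alpha = 0.25
  expect_lte(mean(qmin <= 0.25), 0.25 * 1.5)
  expect_gt(median(qmin), 0.5)
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(46, {
    for (i in 1:5) {
      p <- runif(57)
      expect_equal(bh_adjust(p), bh_brute_force(p))
    }
    # monotone nondecreasing in p after sorting
    p <- runif(101)
    q <- bh_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  })
})

test_that("deregression reproduces the hand-worked record and its monotonicity", {
  r <- deregress_ebv(10, r2 = 0.5, h2 = 0.25, c = 0.2)
  expect_equal(r$debv, 20)
  expect_equal(r$weight, 0.75 / ((0.2 + 1) * 0.25))  # = 2.5

  # r2 = 1 with c = 0: weight diverges and is capped with a warning
  expect_warning(rc <- deregress_ebv(10, 1, 0.25, 0), "capped")
  expect_equal(rc$debv, 10)
  expect_equal(rc$weight, 1e6)

  # weight strictly increases with r2 at fixed h2, c
  w <- deregress_ebv(1, seq(0.1, 0.9, by = 0.1), 0.3, 0.2)$weight
  expect_true(all(diff(w) > 0))
  expect_error(deregress_ebv(1, 0, 0.3, 0.2), "r2")
})

test_that("parent-adjusted deregression strips the parent average", {
  base <- deregress_ebv(12, 0.6, 0.3, 0.2, mode = "parent_adjusted",
                        ebv_sire = 0, ebv_dam = 0,
                        r2_sire = 0.5, r2_dam = 0.5)
  expect_true(is.finite(base$debv) && base$weight > 0)
  # a high parent average should pull the deregressed record down
  high_pa <- deregress_ebv(12, 0.6, 0.3, 0.2, mode = "parent_adjusted",
                           ebv_sire = 20, ebv_dam = 20,
                           r2_sire = 0.5, r2_dam = 0.5)
  expect_lt(high_pa$debv, base$debv)
})

test_that("the Poisson scan is calibrated on unstructured data and on constants", {
  # allele counts are binomial (bounded), so the Poisson Wald test runs
  # conservative rather than exactly uniform on unstructured data: no
  # inflation and at most nominal tail mass
  g <- hwe_genotypes(300, 400, seed = 51)
  ps <- poisson_birthdate_scan(g)
  expect_lte(genomic_inflation(ps$p_value), 1.1)
  expect_lte(mean(ps$p_value < 0.05), 0.07)

  gc <- hwe_genotypes(50, 2, seed = 52)
  gc$calls[, 1] <- 2
  psc <- poisson_birthdate_scan(gc)
  expect_lt(abs(psc$ase[psc$snp == "snp1"]), 1e-8)
  expect_gt(psc$p_value[psc$snp == "snp1"], 0.99)
})
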