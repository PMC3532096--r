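test_that("ase_variance is 2pq alpha^2 and vanishes at fixation", {
  expect_equal(ase_variance(0.5, 1), 0.5)
  expect_equal(ase_variance(0, 3), 0)
  expect_equal(ase_variance(1, -7), 0)
  expect_error(ase_variance(1.2, 1), "\\[0, 1\\]")

  # summed over independent loci ~ var(Z alpha) within 10%
  g <- hwe_genotypes(2000, 300, seed = 91)
  p <- colMeans(g$calls) / 2
  alpha <- withr::with_seed(92, rnorm(300, 0, 0.1))
  direct <- var(as.numeric(sweep(g$calls, 2, 2 * p) %*% alpha))
  expect_lt(abs(sum(ase_variance(p, alpha)) / direct - 1), 0.1)
})

test_that("rank_top_snps selects by variance with documented tie-breaking", {
  g <- hwe_genotypes(30, 20, seed = 93)
  p <- colMeans(g$calls) / 2
  ase <- withr::with_seed(94, rnorm(20))
  scan <- scan_result(g$map, p, ase)
  top5 <- rank_top_snps(scan, k = 5)
  expect_equal(top5, scan$snp[order(-scan$var_2pqa2)][1:5])
  expect_equal(length(rank_top_snps(scan, k = 20)), 20)
  expect_error(rank_top_snps(scan, k = 21), "1..20")

  # the published operating point: 2.11% of 44,817 rounds to 946
  expect_equal(round(0.0211 * 44817), 946)

  # stability: adding zero-variance SNPs never changes the selected set
  map2 <- rbind(g$map, data.frame(snp = "null1", chrom = "2", pos = 1L,
                                  allele_counted = "A", allele_other = "B"))
  scan2 <- scan_result(map2, c(p, 0.5), c(ase, 0))
  expect_equal(rank_top_snps(scan2, k = 5), top5)
})

test_that("signed LD correlations match brute force and flag degenerate loci", {
  g <- hwe_genotypes(40, 10, seed = 95)
  V <- ld_signed_correlation(g, g$map$snp)
  brute <- matrix(NA_real_, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    brute[i, j] <- cor(g$calls[, i], g$calls[, j])
  }
  expect_lt(max(abs(V - brute)), 1e-12)
  expect_equal(unname(diag(V)), rep(1, 10))

  g$calls[, 2] <- g$calls[, 1]  # duplicated column: off-diagonal exactly 1
  V2 <- ld_signed_correlation(g, g$map$snp)
  expect_equal(V2[1, 2], 1)

  g$calls[, 3] <- 2
  expect_error(ld_signed_correlation(g, g$map$snp), "zero-variance")
})

test_that("perfect-LD pruning keeps the first SNP of each planted run", {
  g <- hwe_genotypes(50, 12, seed = 96)
  # plant two runs: snps 3-5 identical, snps 9-10 sign-flipped copies
  g$calls[, 4] <- g$calls[, 3]
  g$calls[, 5] <- g$calls[, 3]
  g$calls[, 10] <- 2 - g$calls[, 9]
  pruned <- prune_perfect_ld(g, g$map$snp)
  expect_equal(setdiff(g$map$snp, pruned), c("snp4", "snp5", "snp10"))

  # no perfect LD: input unchanged
  g2 <- hwe_genotypes(50, 6, seed = 97)
  expect_equal(prune_perfect_ld(g2, g2$map$snp), g2$map$snp)
})

test_that("GLS intensity regression reduces to OLS at V = I and standardizes scale", {
  sim <- simulate_ase_response(300, c(0.8, -0.4), seed = 98)
  est <- selection_intensity_gls(sim$birth_ases, sim$trait_ases, sim$p)
  x1 <- sim$p * (1 - sim$p) * sim$trait_ases[, 1] / sd(sim$trait_ases[, 1])
  ols <- summary(lm(sim$birth_ases ~ x1))$coefficients
  expect_equal(est$traits$i_hat[1], ols[2, 1], tolerance = 1e-10)
  expect_equal(est$traits$se[1], ols[2, 2], tolerance = 1e-10)
  expect_equal(est$traits$p_value[1], ols[2, 4], tolerance = 1e-10)

  # invariant to rescaling all of a trait's ASEs by a positive constant
  scaled <- sim$trait_ases
  scaled[, 2] <- scaled[, 2] * 37
  est2 <- selection_intensity_gls(sim$birth_ases, scaled, sim$p)
  expect_equal(est2$traits$i_hat, est$traits$i_hat, tolerance = 1e-10)

  expect_error(selection_intensity_gls(sim$birth_ases, sim$trait_ases,
                                       sim$p, V = matrix(1, 300, 300)),
               "singular|positive definite")
})

test_that("regressing birth ASEs on themselves dominates every other trait", {
  sim <- simulate_ase_response(400, c(1, 0.3, 0), seed = 99)
  pq <- sim$p * (1 - sim$p)
  # treat the birth-date ASE itself as a 'trait': its regressor is pq * birth
  traits <- cbind(sim$trait_ases, birth = sim$birth_ases / pq)
  est <- selection_intensity_gls(sim$birth_ases, traits, sim$p)
  r2 <- est$traits$adjusted_R2
  expect_equal(which.max(r2), which(est$traits$trait == "birth"))
})

test_that("intensity signs and ordering are recovered under the response model", {
  ok <- withr::with_seed(100, {
    vapply(1:25, function(i) {
      sim <- simulate_ase_response(935, c(1, 0.3, 0))
      est <- selection_intensity_gls(sim$birth_ases, sim$trait_ases, sim$p)
      ih <- est$traits$i_hat
      ih[1] > 0 && ih[2] > 0 && ih[1] > ih[2] && abs(ih[2]) > abs(ih[3])
    }, NA)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("genetic trends distinguish linear from rise-and-fall trajectories", {
  bd <- seq(1960, 2000, length.out = 120)
  lin <- genetic_trend(2.5 * (bd - 1980), bd)
  expect_equal(lin$quadratic$coefficients[[3]], 0, tolerance = 1e-8)
  expect_equal(lin$linear$adjusted_R2, 1, tolerance = 1e-10)
  expect_equal(lin$slope_per_year, 2.5, tolerance = 1e-10)

  withr::with_seed(101, {
    rise_fall <- 30 - 0.08 * (bd - 1985)^2 + rnorm(120, 0, 2)
  })
  rf <- genetic_trend(rise_fall, bd)
  expect_lt(rf$quadratic$aic, rf$linear$aic)
  expect_equal(rf$preferred, "quadratic")
  expect_gte(rf$quadratic$r2, rf$linear$r2)

  expect_error(genetic_trend(1:3, c(1, 2, 3)), "at least 4")
  expect_error(genetic_trend(1:10, rep(2000, 10)), "constant")

  # permuted birth dates: model p-values approximately uniform
  pvals <- withr::with_seed(102, {
    y <- 2.5 * (bd - 1980) + rnorm(120, 0, 10)
    vapply(1:200, function(i) genetic_trend(y, sample(bd))$linear$p_value, 0)
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("gene windows hit by distance with 1-based inclusive coordinates", {
  snps <- data.frame(snp = c("s1", "s2", "s3"), chrom = "1",
                     pos = c(10000, 250000, 110000))
  genes <- data.frame(gene = "G1", chrom = "1", start = 100000, end = 120000)
  hits <- genes_near_snps(snps, genes, window = 100000)
  expect_setequal(hits$snp, c("s1", "s3"))
  expect_equal(hits$distance_bp[hits$snp == "s1"], 90000)
  expect_equal(hits$distance_bp[hits$snp == "s3"], 0)   # inside the gene

  # interval orientation / strand has no effect on hits
  genes_rev <- data.frame(gene = "G1", chrom = "1", start = 100000,
                          end = 120000, strand = "-")
  expect_equal(genes_near_snps(snps, genes_rev, window = 100000)$distance_bp,
               hits$distance_bp)

  expect_error(genes_near_snps(snps, data.frame(gene = "G", chrom = "chr1",
                                                start = 1, end = 2)),
               "no shared chromosome")
  expect_error(genes_near_snps(snps, data.frame(gene = "G", chrom = "1",
                                                start = 5, end = 2)),
               "start > end")
})

test_that("BED annotation import converts to 1-based inclusive coordinates", {
  skip_if_not_installed("rtracklayer")
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  writeLines("1\t99999\t120000\tG1", bed)  # 0-based half-open
  ann <- read_gene_annotation(bed)
  expect_equal(ann$start, 100000)
  expect_equal(ann$end, 120000)
  expect_equal(ann$gene, "G1")
})

test_that("manhattan layout is cumulative and monotone within chromosome", {
  fx <- cached_fixture("gblup_oracle")
  g <- fx$g
  scan <- scan_result(g$map, colMeans(g$calls) / 2,
                      withr::with_seed(103, rnorm(n_loci(g))))
  md <- manhattan_data(scan)
  expect_true(all(diff(md$x[md$chrom == "1"]) > 0))
  expect_equal(nrow(md), n_loci(g))
})
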