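test_that("base_allele_freqs averages dosages over the base cohort", {
  calls <- rbind(ind1 = c(0, 2), ind2 = c(1, 2), ind3 = c(2, 2))
  map <- data.frame(snp = c("s1", "s2"), chrom = "1", pos = c(1L, 2L))
  g <- genotype_dataset(calls, map, c(1955, 1960, 1999))
  p <- suppressWarnings(base_allele_freqs(g, c("ind1", "ind2", "ind3")))
  expect_equal(unname(p[1]), 0.5)
  # fixed locus is clamped away from 1 with a warning
  expect_warning(p2 <- base_allele_freqs(g, c("ind1", "ind2", "ind3")),
                 "clamped")
  expect_lt(unname(p2[2]), 1)
  expect_error(base_allele_freqs(g, character(0)), "empty")
  expect_equal(earliest_cohort(g, 2), c("ind1", "ind2"))
})

test_that("VanRaden GRM matches the hand-worked one-SNP example", {
  calls <- rbind(a = 0, b = 2)
  colnames(calls) <- "s1"
  g <- genotype_dataset(calls, data.frame(snp = "s1", chrom = "1", pos = 1L),
                        c(2000, 2001))
  G <- grm_vanraden(g, p = 0.5)  # Z = (-1, 1), denom = 0.5
  expect_equal(unname(G$matrix), matrix(c(2, -2, -2, 2), 2))

  # all dosages at 2p => centered to the zero matrix
  g2 <- hwe_genotypes(5, 4, seed = 3)
  g2$calls[] <- rep(1, length(g2$calls))
  G2 <- grm_vanraden(g2, p = rep(0.5, 4))
  expect_equal(max(abs(G2$matrix)), 0)
})

test_that("GRM diagonals centre near 1 on non-inbred founders and entries are permutation-equivariant", {
  g <- hwe_genotypes(80, 400, seed = 11)
  p <- colMeans(g$calls) / 2
  G <- grm_vanraden(g, p)
  expect_lt(abs(mean(diag(G$matrix)) - 1), 0.05)

  # invariant under locus permutation, equivariant under animal permutation
  perm <- withr::with_seed(5, sample(n_loci(g)))
  Gp <- grm_vanraden(subset_genotypes(g, loci = perm), p[perm])
  expect_equal(Gp$matrix, G$matrix, tolerance = 1e-12)
  aperm <- withr::with_seed(6, sample(n_animals(g)))
  Ga <- grm_vanraden(subset_genotypes(g, animals = aperm), p)
  expect_equal(Ga$matrix, G$matrix[aperm, aperm], tolerance = 1e-12)
})

test_that("Balding-Nichols kinship behaves at its extremes", {
  m <- 50
  base <- withr::with_seed(8, rbinom(m, 1, 0.5) * 2)  # homozygous pattern
  calls <- rbind(a = base, b = base, c = 2 - base,
                 d = rep(1, m), e = rep(1, m), f = rep(1, m))
  colnames(calls) <- paste0("s", seq_len(m))
  g <- genotype_dataset(calls,
                        data.frame(snp = colnames(calls), chrom = "1",
                                   pos = seq_len(m)),
                        birth_date = rep(2000, 6))
  K <- balding_nichols_kinship(g)$matrix
  # identical rows: off-diagonal equals diagonal for that pair
  expect_equal(K["a", "b"], K["a", "a"])
  # opposite homozygotes at every SNP: the minimal pairwise value
  off <- K[upper.tri(K)]
  expect_equal(min(off), K["a", "c"])

  gm <- g
  gm$calls[, 1] <- 2
  expect_error(balding_nichols_kinship(gm), "monomorphic")
})

test_that("within-family Balding-Nichols kinship exceeds between-family", {
  fx <- cached_fixture("neutral_null")
  pop <- fx$pop
  ped <- pop$pedigree
  # half-sib families: offspring grouped by sire
  sires <- ped$sire[match(rownames(fx$g$calls), ped$animal)]
  keep <- sires != "0"
  K <- balding_nichols_kinship(fx$g)$matrix[keep, keep]
  fam <- sires[keep]
  same <- outer(fam, fam, "==") & upper.tri(K)
  diff <- !outer(fam, fam, "==") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff]))
})

test_that("pedigree inbreeding reproduces textbook coefficients", {
  # founders -> full sibs -> their offspring: F = 0.25
  ped <- pedigree(c("gs", "gd", "s", "d", "x"),
                  c("0", "0", "gs", "gs", "s"),
                  c("0", "0", "gd", "gd", "d"))
  f <- pedigree_inbreeding(ped)
  expect_equal(unname(f[c("gs", "gd", "s", "d")]), rep(0, 4))
  expect_equal(unname(f["x"]), 0.25)

  # half sibs (shared sire only): F = 0.125
  ped2 <- pedigree(c("gs", "gd1", "gd2", "s", "d", "x"),
                   c("0", "0", "0", "gs", "gs", "s"),
                   c("0", "0", "0", "gd1", "gd2", "d"))
  expect_equal(unname(pedigree_inbreeding(ped2)["x"]), 0.125)

  # offspring of unrelated non-inbred parents: F = 0
  ped3 <- pedigree(c("s", "d", "x"), c("0", "0", "s"), c("0", "0", "d"))
  expect_equal(unname(pedigree_inbreeding(ped3)["x"]), 0)
})

test_that("genomic F is the GRM diagonal minus one", {
  g <- hwe_genotypes(10, 100, seed = 12)
  G <- grm_vanraden(g, colMeans(g$calls) / 2)
  f <- genomic_inbreeding(G)
  expect_equal(as.numeric(f), unname(diag(G$matrix)) - 1)
  expect_error(genomic_inbreeding(balding_nichols_kinship(g)), "VanRaden")
})

test_that("pedigree and genomic inbreeding agree in direction on deep pedigrees", {
  fx <- cached_fixture("neutral_null")
  pop <- fx$pop
  ids <- rownames(fx$g$calls)
  fp <- pedigree_inbreeding(pop$pedigree)[ids]
  p <- base_allele_freqs(fx$g, earliest_cohort(fx$g, 60))
  fg <- genomic_inbreeding(grm_vanraden(fx$g, p))
  slope <- coef(lm(as.numeric(fp) ~ as.numeric(fg)))[2]
  expect_gt(slope, 0)
})

test_that("genomic F varies more than pedigree F under selection", {
  fx <- cached_fixture("selected_sweep")
  ids <- rownames(fx$g$calls)
  fp <- pedigree_inbreeding(fx$pop$pedigree)[ids]
  p <- base_allele_freqs(fx$g, earliest_cohort(fx$g, 60))
  fg <- genomic_inbreeding(grm_vanraden(fx$g, p))
  expect_gt(var(as.numeric(fg)), var(as.numeric(fp)))
})

test_that("GRM principal components separate diverged subpopulations", {
  # identity: equal eigenvalues, orthonormal scores after unscaling
  G <- relationship_matrix(diag(10), "grm_vanraden")
  pc <- grm_principal_components(G, 3)
  expect_equal(pc$values, rep(1, 10))
  expect_equal(unname(crossprod(pc$scores)), diag(3), tolerance = 1e-8)
  expect_error(grm_principal_components(G, 0), "positive")

  # spectral identity: full reconstruction
  g <- hwe_genotypes(12, 60, seed = 13)
  Gm <- grm_vanraden(g, colMeans(g$calls) / 2)
  e <- eigen(Gm$matrix, symmetric = TRUE)
  rec <- e$vectors %*% diag(e$values) %*% t(e$vectors)
  expect_equal(rec, unname(Gm$matrix), tolerance = 1e-8)

  # two diverged herds: PC1 separates them without overlap
  fx <- cached_fixture("confounded_sampling")
  g2 <- impute_missing(fx$g)
  herd <- fx$pop$herd[match(rownames(g2$calls),
                            rownames(fx$pop$genotypes$calls))]
  G2 <- grm_vanraden(g2, colMeans(g2$calls) / 2)
  pc2 <- grm_principal_components(G2, 2)
  r1 <- range(pc2$scores[herd == 1, 1])
  r2 <- range(pc2$scores[herd == 2, 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
})

test_that("parent-offspring GRM entries average near one half", {
  fx <- cached_fixture("neutral_null")
  pop <- fx$pop
  g <- fx$g
  p <- base_allele_freqs(g, earliest_cohort(g, 60))
  G <- grm_vanraden(g, p)$matrix
  ids <- rownames(g$calls)
  ped <- pop$pedigree
  i <- match(ids, ped$animal)
  pairs <- cbind(match(ids, ids), match(ped$sire[i], ids))
  pairs <- pairs[!is.na(pairs[, 2]), , drop = FALSE]
  skip_if(nrow(pairs) < 20)
  expect_lt(abs(mean(G[pairs]) - 0.5), 0.05)
})

test_that("relationship matrix and inbreeding writers round trip", {
  g <- hwe_genotypes(8, 40, seed = 14)
  G <- grm_vanraden(g, colMeans(g$calls) / 2)
  dir <- withr::local_tempdir()
  write_relationship_matrix(G, file.path(dir, "g.tsv"))
  G2 <- read_relationship_matrix(file.path(dir, "g.tsv"))
  expect_equal(G2$matrix, G$matrix, tolerance = 1e-6)
  write_inbreeding(file.path(dir, "f.tsv"),
                   f_pedigree = NULL, f_genomic = genomic_inbreeding(G))
  f <- read.table(file.path(dir, "f.tsv"), header = TRUE, sep = "\t")
  expect_equal(f$F_genomic, unname(diag(G$matrix)) - 1, tolerance = 1e-6)
})
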