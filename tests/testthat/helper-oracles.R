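# Independent oracles and shared fixtures for the suite.

# Build each registered fixture at most once per test run.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, seed = 20111) {
  key <- paste(name, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture(name, seed = seed)
  }
  .fixture_cache[[key]]
}

# Unstructured Hardy-Weinberg genotype dataset (no pedigree).
hwe_genotypes <- function(n, m, p = NULL, seed = 1, birth_date = NULL) {
  withr::with_seed(seed, {
    p <- p %||% runif(m, 0.2, 0.8)
    calls <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n,
                    dimnames = list(paste0("ind", seq_len(n)),
                                    paste0("snp", seq_len(m))))
    storage.mode(calls) <- "double"
    map <- data.frame(snp = colnames(calls), chrom = "1",
                      pos = seq_len(m) * 1e4, stringsAsFactors = FALSE)
    genotype_dataset(calls, map,
                     birth_date %||% (1990 + runif(n, 0, 20)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive Mendelian-consistency check of a simulated population: every
# offspring dosage must be reachable from its parents' dosages.
mendelian_consistent <- function(pop) {
  ped <- pop$pedigree
  calls <- pop$genotypes$calls
  idx <- setNames(seq_len(nrow(ped)), ped$animal)
  offspring <- which(ped$sire != "0" & ped$dam != "0")
  for (i in offspring) {
    cc <- calls[idx[ped$animal[i]], ]
    ds <- calls[idx[ped$sire[i]], ]
    dd <- calls[idx[ped$dam[i]], ]
    lo <- (ds == 2) + (dd == 2)
    hi <- 2 - ((ds == 0) + (dd == 0))
    if (any(cc < lo | cc > hi, na.rm = TRUE)) return(FALSE)
  }
  TRUE
}
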