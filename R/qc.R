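#' Hardy-Weinberg chi-square statistic (1 df)
#'
#' Compares observed genotype counts with the Hardy-Weinberg expectation at
#' the sample allele frequency. Vectorized over loci.
#'
#' @param n_AA,n_AB,n_BB non-negative genotype counts.
#' @return the chi-square statistic (1 degree of freedom).
#' @export
hwe_chi_square <- function(n_AA, n_AB, n_BB) {
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("negative genotype counts")
  n <- n_AA + n_AB + n_BB
  if (any(n == 0)) stop("total genotype count is zero")
  p <- (2 * n_AA + n_AB) / (2 * n)
  e <- cbind(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
  o <- cbind(n_AA, n_AB, n_BB)
  stat <- rowSums(ifelse(e > 0, (o - e)^2 / e, 0))
  unname(stat)
}

hwe_stat_for_dataset <- function(calls) {
  intish <- !is.na(calls) & abs(calls - round(calls)) < 1e-9
  nAA <- colSums(calls == 2 & intish, na.rm = TRUE)
  nAB <- colSums(calls == 1 & intish, na.rm = TRUE)
  nBB <- colSums(calls == 0 & intish, na.rm = TRUE)
  tot <- nAA + nAB + nBB
  stat <- rep(NA_real_, ncol(calls))
  ok <- tot > 0
  stat[ok] <- hwe_chi_square(nAA[ok], nAB[ok], nBB[ok])
  stat
}

#' Quality-control filter for genotype datasets
#'
#' Applies, in order: SNP call rate, animal call rate, minor allele
#' frequency, and Hardy-Weinberg chi-square. MAF and the HWE statistic are
#' computed on non-missing calls after the call-rate filters. The HWE filter
#' is applied to autosomal (and pseudoautosomal) loci only; X-linked loci are
#' exempt. The large default chi-square cutoff targets assay artefacts
#' (e.g. polymorphisms inside copy-number variants) rather than selected loci.
#'
#' @param g a [genotype_dataset()]
#' @param snp_call_min minimum per-SNP call rate (default 0.90)
#' @param animal_call_min minimum per-animal call rate (default 0.95)
#' @param maf_min minimum minor allele frequency (default 0.01)
#' @param hwe_chi2_max maximum HWE chi-square (default 300)
#' @param x_chrom label of the X chromosome (exempt from the HWE filter)
#' @return list with `dataset` (filtered [genotype_dataset()]) and `report`
#'   (class `qc_report`: per-filter removal counts).
#' @export
qc_filter <- function(g, snp_call_min = 0.90, animal_call_min = 0.95,
                      maf_min = 0.01, hwe_chi2_max = 300, x_chrom = "X") {
  stopifnot(snp_call_min >= 0, snp_call_min <= 1,
            animal_call_min >= 0, animal_call_min <= 1,
            maf_min >= 0, maf_min < 0.5, hwe_chi2_max > 0)
  report <- data.frame(filter = c("snp_call_rate", "animal_call_rate",
                                  "maf", "hwe"),
                       removed = 0L, stringsAsFactors = FALSE)

  # 1. SNP call rate
  cr_snp <- colMeans(!is.na(g$calls))
  keep_snp <- cr_snp >= snp_call_min
  report$removed[1] <- sum(!keep_snp)
  if (!any(keep_snp)) stop("empty dataset: all SNPs removed by QC")
  g <- subset_genotypes(g, loci = which(keep_snp))

  # 2. animal call rate
  cr_ani <- rowMeans(!is.na(g$calls))
  keep_ani <- cr_ani >= animal_call_min
  report$removed[2] <- sum(!keep_ani)
  if (!any(keep_ani)) stop("empty dataset: all animals removed by QC")
  g <- subset_genotypes(g, animals = which(keep_ani))

  # 3. MAF on non-missing calls
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= maf_min
  report$removed[3] <- sum(!keep_maf)
  if (!any(keep_maf)) stop("empty dataset: all SNPs removed by QC")
  g <- subset_genotypes(g, loci = which(keep_maf))

  # 4. HWE chi-square, autosomes only
  stat <- hwe_stat_for_dataset(g$calls)
  on_x <- g$map$chrom == x_chrom
  keep_hwe <- on_x | is.na(stat) | stat <= hwe_chi2_max
  report$removed[4] <- sum(!keep_hwe)
  if (!any(keep_hwe)) stop("empty dataset: all SNPs removed by QC")
  g <- subset_genotypes(g, loci = which(keep_hwe))

  class(report) <- c("qc_report", "data.frame")
  list(dataset = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (filters applied in order):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s removed %d\n", x$filter[i], x$removed[i]))
  }
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Impute missing genotype calls
#'
#' `mean_dosage` (default, deterministic) replaces missing calls at a locus
#' by the mean dosage of the non-missing calls; `sample_hwe` draws a genotype
#' from the binomial Hardy-Weinberg distribution at the locus's observed
#' allele frequency. At the sub-percent missingness typical of filtered SNP
#' arrays, downstream relationship matrices and scans are insensitive to the
#' choice.
#'
#' @param g a [genotype_dataset()]
#' @param method `"mean_dosage"` or `"sample_hwe"`
#' @param seed RNG seed for `sample_hwe` (reproducible draws); ignored for
#'   `mean_dosage`.
#' @return the completed [genotype_dataset()] (no missing calls).
#' @export
impute_missing <- function(g, method = c("mean_dosage", "sample_hwe"),
                           seed = NULL) {
  method <- match.arg(method)
  calls <- g$calls
  miss_by_locus <- colSums(is.na(calls))
  if (!any(miss_by_locus > 0)) return(g)
  all_missing <- miss_by_locus == nrow(calls)
  if (any(all_missing)) {
    stop("loci with all calls missing: ",
         paste(g$map$snp[all_missing], collapse = ", "))
  }
  fill <- which(miss_by_locus > 0)
  with_seed(seed, {
    for (j in fill) {
      nas <- is.na(calls[, j])
      if (method == "mean_dosage") {
        calls[nas, j] <- mean(calls[!nas, j])
      } else {
        p <- mean(calls[!nas, j]) / 2
        calls[nas, j] <- rbinom(sum(nas), 2L, p)
      }
    }
  })
  g$calls <- calls
  g
}
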