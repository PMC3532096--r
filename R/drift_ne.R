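#' Generation number from birth year
#'
#' `(birth_year - reference) / interval`, fractional values allowed. The
#' defaults (reference 1950, 5-year generation interval) reproduce the
#' generation numbering used for inbreeding regressions on birth-year data;
#' animals born before the reference get negative generations.
#'
#' @param birth_year numeric birth years (decimal years allowed).
#' @param reference reference year mapped to generation 0.
#' @param interval generation interval in years.
#' @return numeric generation numbers.
#' @export
generation_number <- function(birth_year, reference = 1950, interval = 5) {
  if (!all(is.finite(birth_year))) stop("birth_year must be finite")
  (birth_year - reference) / interval
}

#' Effective population size from an inbreeding regression
#'
#' Ordinary least squares of individual inbreeding coefficients on
#' generation number; the slope estimates the per-generation increase
#' `delta_F = 1 / (2 Ne)`, so `Ne = 1 / (2 * slope)` and, by the delta
#' method, `SE(Ne) ~= 2 Ne SE(delta_F)`.
#'
#' @param F per-animal inbreeding coefficients ([pedigree_inbreeding()] or
#'   [genomic_inbreeding()]).
#' @param generations per-animal generation numbers (same order as `F`),
#'   e.g. from [generation_number()].
#' @param subset optional label recorded in the result (which animals the
#'   regression used).
#' @return object of class `ne_estimate`: `delta_F`, `se_delta_F`, `Ne`,
#'   `se_Ne`, `intercept`, `n`, `subset`.
#' @export
ne_from_inbreeding_regression <- function(F, generations, subset = "all") {
  F <- as.numeric(F)
  if (length(F) != length(generations)) stop("F and generations differ in length")
  if (length(F) < 3) stop("need at least 3 animals")
  if (diff(range(generations)) < 1) {
    stop("animals must span at least one generation")
  }
  fit <- lm(F ~ generations)
  sm <- summary(fit)$coefficients
  slope <- sm[2, 1]
  se_slope <- sm[2, 2]
  if (slope <= 0) {
    stop("no inbreeding accumulation: regression slope is ", signif(slope, 3),
         "; Ne is undefined")
  }
  ne <- 1 / (2 * slope)
  structure(list(delta_F = slope, se_delta_F = se_slope,
                 Ne = ne, se_Ne = 2 * ne * se_slope,
                 intercept = sm[1, 1], n = length(F), subset = subset),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne estimate (%s, n = %d):\n", x$subset, x$n))
  cat(sprintf("  delta_F/generation = %.4g +/- %.4g\n", x$delta_F, x$se_delta_F))
  cat(sprintf("  Ne = %.4f +/- %.4f\n", x$Ne, x$se_Ne))
  invisible(x)
}

#' Per-cohort allele frequencies
#'
#' Counted-allele frequencies in two disjoint cohorts (e.g. two adjacent
#' pedigree generations), the input to [drift_test()].
#'
#' @param g a [genotype_dataset()] (missing calls dropped per locus).
#' @param cohort_a,cohort_b disjoint, nonempty animal id sets; `cohort_a` is
#'   the earlier cohort.
#' @return data.frame with columns `snp`, `p1`, `p2`.
#' @export
cohort_allele_freqs <- function(g, cohort_a, cohort_b) {
  if (!length(cohort_a) || !length(cohort_b)) stop("cohorts must be nonempty")
  both <- intersect(cohort_a, cohort_b)
  if (length(both)) {
    stop("animals in both cohorts: ", paste(head(both, 5), collapse = ", "))
  }
  p1 <- colMeans(subset_genotypes(g, animals = cohort_a)$calls, na.rm = TRUE) / 2
  p2 <- colMeans(subset_genotypes(g, animals = cohort_b)$calls, na.rm = TRUE) / 2
  data.frame(snp = g$map$snp, p1 = unname(p1), p2 = unname(p2),
             stringsAsFactors = FALSE)
}

#' Drift-versus-selection test on allele-frequency change
#'
#' Tests, per SNP, whether the observed change in allele frequency between
#' two cohorts exceeds what neutral drift at effective population size `Ne`
#' can plausibly produce. Under neutrality `delta_p = p2 - p1` is treated as
#' normal with mean 0 and variance `p1 (1 - p1) / (2 Ne)` per generation for
#' autosomes, `p1 (1 - p1) / (1.5 Ne)` for the X chromosome; the earlier
#' cohort's frequency `p1` supplies the variance. A SNP is flagged as
#' selected when the two-sided `-log10(p)` exceeds `threshold_log10_p`
#' (default 8, i.e. a 99.999999% confidence interval). Cohorts more than one
#' generation apart are handled by scaling the drift variance by
#' `generations`. Loci fixed in the earlier cohort have zero drift variance
#' and are skipped with a warning. Finite-cohort binomial sampling noise is
#' deliberately *not* added to the drift variance.
#'
#' @param p1,p2 earlier/later cohort frequencies (e.g. from
#'   [cohort_allele_freqs()]).
#' @param Ne effective population size (> 0).
#' @param chrom per-SNP chromosome labels (used to spot X-linked SNPs);
#'   default: all autosomal.
#' @param threshold_log10_p flagging threshold on `-log10(p)`.
#' @param generations cohort gap in generations (variance multiplier).
#' @param snp optional SNP ids.
#' @param x_chrom X chromosome label.
#' @return data.frame of class `drift_test_result` with per-SNP `p1`, `p2`,
#'   `delta_p`, `z`, `minus_log10_p`, `flagged`; attribute `fraction_flagged`
#'   is the flagged share of testable SNPs.
#' @export
drift_test <- function(p1, p2, Ne, chrom = NULL, threshold_log10_p = 8,
                       generations = 1, snp = NULL, x_chrom = "X") {
  if (Ne <= 0) stop("Ne must be positive")
  if (length(p1) != length(p2)) stop("p1 and p2 differ in length")
  m <- length(p1)
  chrom <- chrom %||% rep("1", m)
  snp <- snp %||% paste0("snp", seq_len(m))
  fixed <- p1 <= 0 | p1 >= 1
  if (any(fixed)) {
    warning(sum(fixed), " loci fixed in the earlier cohort skipped ",
            "(zero drift variance)")
  }
  denom <- ifelse(chrom == x_chrom, 1.5 * Ne, 2 * Ne)
  v <- generations * p1 * (1 - p1) / denom
  z <- rep(NA_real_, m)
  z[!fixed] <- (p2[!fixed] - p1[!fixed]) / sqrt(v[!fixed])
  # -log10 two-sided normal p, stable for extreme z
  mlp <- -(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
  flagged <- !is.na(mlp) & mlp > threshold_log10_p
  out <- data.frame(snp = snp, chrom = chrom, p1 = p1, p2 = p2,
                    delta_p = p2 - p1, z = z, minus_log10_p = mlp,
                    flagged = flagged, stringsAsFactors = FALSE)
  class(out) <- c("drift_test_result", "data.frame")
  attr(out, "fraction_flagged") <- mean(flagged[!fixed])
  attr(out, "threshold_log10_p") <- threshold_log10_p
  attr(out, "Ne") <- Ne
  out
}

#' @export
print.drift_test_result <- function(x, ...) {
  tested <- sum(!is.na(x$z))
  cat(sprintf("drift test: %d SNPs (%d testable), Ne = %.2f, threshold -log10(p) = %g\n",
              nrow(x), tested, attr(x, "Ne"), attr(x, "threshold_log10_p")))
  cat(sprintf("  fraction flagged as exceeding drift: %.4f\n",
              attr(x, "fraction_flagged")))
  invisible(x)
}

#' Write a drift-test TSV plus one-line summary
#' @param res a `drift_test_result`
#' @param path output TSV
#' @return `path`, invisibly.
#' @export
write_drift_test <- function(res, path) {
  write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("fraction_flagged\t%.6f\n", attr(res, "fraction_flagged")),
      file = paste0(path, ".summary"))
  invisible(path)
}
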