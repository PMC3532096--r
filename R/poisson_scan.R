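#' Naive Poisson allele-count scan on birth date
#'
#' The baseline the mixed models exist to replace: for each SNP, a Poisson
#' GLM of the allele count (0/1/2) on birth date, with the Wald p-value for
#' the slope. With any family-biased temporal sampling or population
#' structure this scan is badly miscalibrated (genomic inflation far above
#' 1), because between-family allele-frequency differences are confounded
#' with time; it is provided as a diagnostic contrast for
#' [emmax_scan()].
#'
#' @param g a [genotype_dataset()]; missing calls are dropped per SNP.
#' @param center_year subtracted from birth dates before fitting (numerical
#'   conditioning only; default: mean birth date).
#' @return a [scan_result()] with the per-SNP slope (as `ase`), p- and
#'   q-values, ranked by p-value. Non-converged fits get `NA` p-values.
#' @export
poisson_birthdate_scan <- function(g, center_year = NULL) {
  bd <- g$birth_date - (center_year %||% mean(g$birth_date))
  m <- ncol(g$calls)
  slope <- rep(NA_real_, m)
  pval <- rep(NA_real_, m)
  n_fail <- 0L
  for (j in seq_len(m)) {
    cj <- g$calls[, j]
    ok <- !is.na(cj)
    if (sum(ok) < 3) next
    fit <- tryCatch(
      suppressWarnings(glm.fit(cbind(1, bd[ok]), cj[ok], family = poisson())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_fail <- n_fail + 1L; next }
    # Wald test from the weighted information matrix
    Xj <- cbind(1, bd[ok])
    info <- crossprod(Xj * sqrt(fit$weights))
    cov2 <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov2)) { n_fail <- n_fail + 1L; next }
    slope[j] <- fit$coefficients[2]
    z <- slope[j] / sqrt(cov2[2, 2])
    pval[j] <- 2 * pnorm(-abs(z))
  }
  if (n_fail > 0) {
    message(n_fail, " SNPs failed to converge; p-values left missing")
  }
  freq <- colMeans(g$calls, na.rm = TRUE) / 2
  scan_result(g$map, freq = freq, ase = slope, p_value = pval,
              rank_by = "p_value")
}
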