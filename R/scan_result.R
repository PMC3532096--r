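#' Per-SNP scan result
#'
#' Normalized per-SNP output shared by the GBLUP backsolve, EMMAX, BayesC-pi
#' and Poisson scans: allele substitution effect (ASE, in units of the
#' dependent variable per copy of the counted allele), the additive variance
#' `2 p (1 - p) alpha^2` it implies, and (for scans that test) p/q-values.
#' Ranks are 1 = strongest signal; ties break by map order (chromosome, then
#' position), which keeps top-k selections reproducible.
#'
#' @param map SNP map data.frame (`snp`, `chrom`, `pos`).
#' @param freq per-SNP counted-allele frequency used for the variance.
#' @param ase per-SNP allele substitution effect.
#' @param p_value optional per-SNP p-values (`NA` for scans that do not test).
#' @param rank_by `"variance"` (default) or `"p_value"`.
#' @param extra optional data.frame of additional per-SNP columns.
#' @return data.frame of class `scan_result` with columns `snp`, `chrom`,
#'   `pos`, `freq`, `ase`, `var_2pqa2`, `p_value`, `q_value`, `rank`.
#' @export
scan_result <- function(map, freq, ase, p_value = NA_real_,
                        rank_by = c("variance", "p_value"), extra = NULL) {
  rank_by <- match.arg(rank_by)
  var2pq <- ase_variance(freq, ase)
  q <- rep(NA_real_, length(ase))
  if (any(!is.na(p_value))) {
    ok <- !is.na(p_value)
    q[ok] <- bh_adjust(p_value[ok])
  }
  chrom_ord <- match(map$chrom, unique(map$chrom))
  key <- if (rank_by == "variance") -var2pq else p_value
  rk <- integer(length(ase))
  rk[order(key, chrom_ord, map$pos)] <- seq_along(ase)
  out <- data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
                    freq = freq, ase = ase, var_2pqa2 = var2pq,
                    p_value = p_value, q_value = q, rank = rk,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  out
}

#' @export
print.scan_result <- function(x, n = 6, ...) {
  cat("scan_result:", nrow(x), "SNPs\n")
  top <- x[order(x$rank), ][seq_len(min(n, nrow(x))), ]
  print.data.frame(top, digits = 4)
  invisible(x)
}

#' Write a scan result as TSV (Manhattan-ready)
#' @param scan a [scan_result()]
#' @param path output TSV path
#' @return `path`, invisibly.
#' @export
write_scan_result <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
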