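#' Additive variance implied by an allele substitution effect
#'
#' `2 p (1 - p) alpha^2` — the per-SNP additive genetic variance for
#' counted-allele frequency `p` and ASE `alpha`. Vectorized.
#'
#' @param p allele frequency in `[0, 1]`.
#' @param alpha allele substitution effect.
#' @return the variance contribution (same length).
#' @export
ase_variance <- function(p, alpha) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p outside [0, 1]")
  2 * p * (1 - p) * alpha^2
}

#' Top SNPs of a scan
#'
#' Selects the `k` strongest SNPs (or a fraction of them) from a
#' [scan_result()], using the scan's own ranking: `2pq alpha^2` for
#' GBLUP/BayesC-pi scans, q-value for testing scans. Ties break by map order
#' (chromosome, position), so the selection is reproducible; SNPs with zero
#' variance can never displace ranked ones.
#'
#' @param scan a [scan_result()].
#' @param k number of SNPs to keep, or
#' @param fraction fraction of SNPs to keep (`k = round(fraction * m)`).
#' @return character vector of SNP ids, in rank order.
#' @export
rank_top_snps <- function(scan, k = NULL, fraction = NULL) {
  m <- nrow(scan)
  if (is.null(k)) {
    if (is.null(fraction)) stop("give k or fraction")
    k <- round(fraction * m)
  }
  if (k <= 0 || k > m) stop("k must lie in 1..", m)
  scan$snp[order(scan$rank)][seq_len(k)]
}

#' Signed LD correlation matrix
#'
#' Pearson correlation between dosage vectors at pairs of SNPs (signed `r`,
#' not `r^2`); unit diagonal.
#'
#' @param g a [genotype_dataset()] with no missing calls.
#' @param snps SNP ids (or indices) to include.
#' @return correlation matrix with SNP ids as dimnames.
#' @export
ld_signed_correlation <- function(g, snps) {
  if (!length(snps)) stop("empty SNP set")
  sub <- subset_genotypes(g, loci = snps)
  if (anyNA(sub$calls)) stop("missing calls present; impute first")
  v <- apply(sub$calls, 2, var)
  if (any(v == 0)) {
    stop("zero-variance SNPs: ",
         paste(head(sub$map$snp[v == 0], 5), collapse = ", "))
  }
  V <- cor(sub$calls)
  dimnames(V) <- list(sub$map$snp, sub$map$snp)
  V
}

#' Prune runs of perfect LD
#'
#' Within each maximal run of map-consecutive SNPs in pairwise perfect LD
#' (`r = +/-1`), keeps only the first SNP. Perfect correlation is transitive,
#' so adjacent-pair checks identify the runs.
#'
#' @param g a [genotype_dataset()] with no missing calls.
#' @param snps SNP ids sorted by chromosome and position.
#' @param tol numerical tolerance on `|r| = 1`.
#' @return pruned character vector of SNP ids (subset of `snps`, order kept).
#' @export
prune_perfect_ld <- function(g, snps, tol = 1e-9) {
  if (length(snps) < 2) return(snps)
  sub <- subset_genotypes(g, loci = snps)
  keep <- rep(TRUE, length(snps))
  for (i in 2:length(snps)) {
    same_chrom <- sub$map$chrom[i] == sub$map$chrom[i - 1]
    if (!same_chrom) next
    r <- cor(sub$calls[, i], sub$calls[, i - 1])
    # |r| = 1 is transitive, so perfect correlation with the previous SNP
    # implies perfect correlation with the run head
    if (is.finite(r) && abs(r) >= 1 - tol) keep[i] <- FALSE
  }
  snps[keep]
}

#' Relative selection intensities from ASE regressions (GLS)
#'
#' Reconstructs which traits drove the observed allele-frequency changes.
#' Under truncation selection the expected per-generation change is
#' `delta_q = -i p q a / sigma_p`; with zero dominance the trait ASE proxies
#' `a`, so the regressor for each trait is `x_j = p_j q_j ASE_j / sigma_ASE`
#' (standardized by that trait's ASE standard deviation over the SNP set).
#' Birth-date ASEs are regressed on each trait's regressor by generalized
#' least squares with error covariance proportional to the signed LD matrix
#' `V`, giving a signed estimate of the relative selection intensity per
#' trait. A joint multi-trait fit is also run, but only its adjusted `R^2`
#' is trustworthy (multicollinearity between trait ASEs; the condition
#' number is reported).
#'
#' @param birth_ases per-SNP birth-date ASEs over the (pruned) SNP set.
#' @param trait_ases matrix (SNPs x traits) of trait ASEs, column names =
#'   trait names.
#' @param p per-SNP allele frequencies.
#' @param V LD correlation matrix from [ld_signed_correlation()] (positive
#'   definite; `V = I` reduces the fit to OLS).
#' @param alpha_bonferroni reporting threshold; default `0.05 / n_traits`.
#' @return object of class `intensity_estimate`: data.frame `traits` with
#'   `i_hat`, `se`, `p_value`, `adjusted_R2`, `significant`; plus
#'   `joint_adjusted_R2`, `joint_condition_number`, `n_snps`.
#' @export
selection_intensity_gls <- function(birth_ases, trait_ases, p, V = NULL,
                                    alpha_bonferroni = NULL) {
  trait_ases <- as.matrix(trait_ases)
  m <- length(birth_ases)
  if (nrow(trait_ases) != m || length(p) != m) {
    stop("mismatched SNP sets across inputs")
  }
  if (is.null(colnames(trait_ases))) {
    colnames(trait_ases) <- paste0("trait", seq_len(ncol(trait_ases)))
  }
  if (is.null(V)) V <- diag(m)
  if (nrow(V) != m) stop("mismatched SNP sets: V is ", nrow(V), " x ", ncol(V))
  L <- tryCatch(chol(V), error = function(e)
    stop("V is singular or not positive definite; prune perfect LD first"))
  whiten <- function(A) backsolve(L, A, transpose = TRUE)

  pq <- p * (1 - p)
  X <- sweep(trait_ases, 2L, apply(trait_ases, 2, sd), "/") * pq
  yw <- whiten(cbind(birth_ases))
  ones_w <- whiten(cbind(rep(1, m)))
  n_tr <- ncol(X)
  alpha_bonferroni <- alpha_bonferroni %||% (0.05 / n_tr)

  fit_one <- function(Xcols) {
    Xw <- cbind(ones_w, whiten(Xcols))
    qrX <- qr(Xw)
    beta <- qr.coef(qrX, yw)
    res <- qr.resid(qrX, yw)
    pp <- ncol(Xw)
    sigma2 <- sum(res^2) / (m - pp)
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * diag(XtXinv))
    tss <- sum(qr.resid(qr(ones_w), yw)^2)
    r2 <- 1 - sum(res^2) / tss
    adj <- 1 - (1 - r2) * (m - 1) / (m - pp)
    list(beta = beta, se = se, sigma2 = sigma2, adj_r2 = adj, df = m - pp)
  }

  rows <- lapply(seq_len(n_tr), function(t) {
    f <- fit_one(X[, t, drop = FALSE])
    tstat <- f$beta[2] / f$se[2]
    data.frame(trait = colnames(X)[t], i_hat = f$beta[2], se = f$se[2],
               p_value = 2 * pt(-abs(tstat), f$df), adjusted_R2 = f$adj_r2,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$significant <- tab$p_value < alpha_bonferroni

  joint <- fit_one(X)
  structure(list(traits = tab,
                 joint_adjusted_R2 = joint$adj_r2,
                 joint_coefficients = setNames(as.numeric(joint$beta[-1]),
                                               colnames(X)),
                 joint_condition_number = kappa(crossprod(whiten(X)),
                                                exact = TRUE),
                 alpha_bonferroni = alpha_bonferroni,
                 n_snps = m),
            class = "intensity_estimate")
}

#' @export
print.intensity_estimate <- function(x, ...) {
  cat("selection intensity estimates (GLS over", x$n_snps, "SNPs):\n")
  print.data.frame(x$traits, digits = 4, row.names = FALSE)
  cat(sprintf("  joint fit adjusted R2 = %.4f (condition number %.3g; individual joint\n",
              x$joint_adjusted_R2, x$joint_condition_number))
  cat("  coefficients unreliable under multicollinearity)\n")
  invisible(x)
}

#' Genetic trend of breeding values on birth date
#'
#' Fits linear and quadratic regressions of (deregressed) breeding values on
#' birth date and reports both, with AIC, adjusted `R^2` and the model
#' F-test p-value, to characterize whether a trait's genetic mean moved
#' linearly or reversed direction over the sampled span.
#'
#' @param debv numeric breeding values (>= 4 observations).
#' @param birth_date decimal-year birth dates (non-constant).
#' @return object of class `trend_fit`: `linear` and `quadratic` sublists
#'   with `coefficients`, `aic`, `adjusted_R2`, `p_value`; plus
#'   `preferred` (`"quadratic"` iff its AIC is lower).
#' @export
genetic_trend <- function(debv, birth_date) {
  if (length(debv) < 4) stop("need at least 4 observations")
  if (var(birth_date) == 0) stop("birth dates are constant")
  t0 <- birth_date - mean(birth_date)
  f1 <- lm(debv ~ t0)
  f2 <- lm(debv ~ t0 + I(t0^2))
  pack <- function(f) {
    sm <- summary(f)
    fs <- sm$fstatistic
    list(coefficients = coef(f), aic = AIC(f),
         adjusted_R2 = sm$adj.r.squared,
         r2 = sm$r.squared,
         p_value = if (is.null(fs)) NA_real_ else
           unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
  }
  l1 <- pack(f1); l2 <- pack(f2)
  structure(list(linear = l1, quadratic = l2,
                 slope_per_year = unname(coef(f1)[2]),
                 preferred = if (l2$aic < l1$aic) "quadratic" else "linear"),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("genetic trend: linear slope %.4g units/yr (AIC %.1f, adj R2 %.3f, p %.3g)\n",
              x$slope_per_year, x$linear$aic, x$linear$adjusted_R2,
              x$linear$p_value))
  cat(sprintf("  quadratic AIC %.1f (adj R2 %.3f); preferred: %s\n",
              x$quadratic$aic, x$quadratic$adjusted_R2, x$preferred))
  invisible(x)
}

#' Genes within a window of selected SNPs
#'
#' Reports every (SNP, gene) pair whose distance is at most `window` base
#' pairs, with distance 0 when the SNP lies inside the gene. Coordinates are
#' 1-based inclusive on both sides; strand and interval orientation are
#' ignored.
#'
#' @param snps data.frame with columns `snp`, `chrom`, `pos` (e.g. map rows
#'   of the top-ranked SNPs).
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (see [read_gene_annotation()]).
#' @param window maximum distance in bp (default 100 kb).
#' @return data.frame with columns `snp`, `gene`, `chrom`, `distance_bp`.
#' @export
genes_near_snps <- function(snps, genes, window = 100000) {
  stopifnot(all(c("snp", "chrom", "pos") %in% names(snps)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) stop("gene intervals with start > end")
  sc <- unique(as.character(snps$chrom))
  gc <- unique(as.character(genes$chrom))
  if (!length(intersect(sc, gc))) {
    stop("no shared chromosome names between map and annotation; ",
         "annotation has: ", paste(head(gc, 10), collapse = ", "))
  }
  out <- list()
  for (ch in intersect(sc, gc)) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    gn <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(s) || !nrow(gn)) next
    d <- outer(s$pos, gn$start, function(p, st) st - p)   # gene upstream gap
    d2 <- outer(s$pos, gn$end, function(p, en) p - en)    # gene downstream gap
    dist <- pmax(d, d2, 0)
    hit <- which(dist <= window, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[ch]] <- data.frame(snp = s$snp[hit[, 1]], gene = gn$gene[hit[, 2]],
                              chrom = ch,
                              distance_bp = dist[hit],
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(snp = character(), gene = character(),
                      chrom = character(), distance_bp = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read gene annotation from BED or GFF3
#'
#' Thin wrapper over `rtracklayer::import()`; BED's 0-based half-open
#' intervals are converted to the package's 1-based inclusive convention by
#' the importer. Gene identifiers come from the `name` (BED) or
#' `ID`/`gene_id`/`Name` (GFF3) attribute.
#'
#' @param path BED or GFF3 file.
#' @param format `"bed"` or `"gff3"` (default: guessed from the extension).
#' @param feature for GFF3, restrict to this `type` (default `"gene"`; NULL
#'   keeps all features).
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path, format = NULL, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gene_annotation needs the rtracklayer package")
  }
  format <- format %||% if (grepl("\\.bed$", path, ignore.case = TRUE))
    "bed" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (format == "gff3" && !is.null(feature) && "type" %in% names(df)) {
    df <- df[df$type == feature, , drop = FALSE]
  }
  id <- df$name %||% df$ID %||% df$gene_id %||% df$Name %||%
    paste0("feature", seq_len(nrow(df)))
  id[is.na(id)] <- paste0("feature", which(is.na(id)))
  data.frame(gene = as.character(id), chrom = as.character(df$seqnames),
             start = df$start, end = df$end, stringsAsFactors = FALSE)
}

#' Manhattan-plot data and helper
#'
#' `manhattan_data()` lays SNPs on a cumulative genome axis (chromosome
#' panels in map order, 30-panel layouts supported naturally);
#' `plot_manhattan()` draws it with base graphics in alternating shades and
#' an optional cutoff line at the value of the `k`-th ranked SNP.
#'
#' @param scan a [scan_result()].
#' @param value which column to plot (`"var_2pqa2"`, `"q_value"`, ...);
#'   q-values are drawn as `-log10`.
#' @return `manhattan_data()`: data.frame `chrom`, `pos`, `x` (cumulative),
#'   `value`.
#' @export
manhattan_data <- function(scan, value = "var_2pqa2") {
  stopifnot(value %in% names(scan))
  chroms <- unique(scan$chrom)
  offset <- 0
  xs <- numeric(nrow(scan))
  for (ch in chroms) {
    i <- scan$chrom == ch
    xs[i] <- offset + scan$pos[i]
    offset <- offset + max(scan$pos[i]) + 1
  }
  v <- scan[[value]]
  if (value %in% c("p_value", "q_value")) v <- -log10(v)
  data.frame(chrom = scan$chrom, pos = scan$pos, x = xs, value = v,
             stringsAsFactors = FALSE)
}

#' @rdname manhattan_data
#' @param top_k draw a horizontal cutoff at the `top_k`-th ranked value.
#' @param ... passed to [graphics::plot()].
#' @export
plot_manhattan <- function(scan, value = "var_2pqa2", top_k = NULL, ...) {
  md <- manhattan_data(scan, value)
  cols <- c("grey25", "steelblue")[1 + (match(md$chrom, unique(md$chrom)) %% 2)]
  graphics::plot(md$x, md$value, col = cols, pch = 20, cex = 0.5,
                 xlab = "genome position", ylab = value, ...)
  if (!is.null(top_k)) {
    cut <- sort(md$value, decreasing = TRUE)[top_k]
    graphics::abline(h = cut, col = "red")
  }
  invisible(md)
}
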