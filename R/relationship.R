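#' Relationship matrix container
#'
#' @param matrix symmetric n x n numeric matrix with animal ids as dimnames.
#' @param kind `"grm_vanraden"` or `"balding_nichols"`.
#' @param base_freqs per-SNP counted-allele frequencies used for
#'   centering/scaling (provenance of the matrix).
#' @return object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(matrix, kind = c("grm_vanraden",
                                                 "balding_nichols"),
                                base_freqs = NULL) {
  kind <- match.arg(kind)
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("relationship matrix is not symmetric")
  }
  if (!is.null(base_freqs) && any(base_freqs <= 0 | base_freqs >= 1)) {
    stop("base_freqs must lie strictly inside (0, 1)")
  }
  structure(list(matrix = matrix, kind = kind, base_freqs = base_freqs),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("relationship_matrix (", x$kind, "): ", nrow(x$matrix), " x ",
      ncol(x$matrix), "\n", sep = "")
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(x$matrix)),
              mean(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

#' Base-generation allele frequencies
#'
#' Counted-allele frequencies estimated from a declared base cohort (e.g. the
#' earliest-born animals), used to anchor the centering and scaling of the
#' genomic relationship matrix. Frequencies are clamped to
#' `[eps, 1 - eps]` with `eps = 1/(4 * n_base)` so that loci monomorphic in
#' the base cohort do not produce degenerate scalings (a warning reports how
#' many were clamped).
#'
#' @param g a [genotype_dataset()] with no missing calls at the base animals
#'   (missing calls are dropped per locus).
#' @param base_animals character ids or indices of the base cohort; the
#'   default `earliest_cohort(g, m)` rule takes the `m` earliest-born animals.
#' @return numeric vector of per-SNP frequencies.
#' @export
base_allele_freqs <- function(g, base_animals) {
  if (length(base_animals) == 0) stop("empty base animal set")
  sub <- subset_genotypes(g, animals = base_animals)
  p <- colMeans(sub$calls, na.rm = TRUE) / 2
  eps <- 1 / (4 * nrow(sub$calls))
  clamped <- p < eps | p > 1 - eps
  if (any(clamped, na.rm = TRUE)) {
    warning(sum(clamped, na.rm = TRUE),
            " loci monomorphic or near-fixed in the base cohort; ",
            "frequencies clamped to [", signif(eps, 3), ", ",
            signif(1 - eps, 3), "]")
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' @rdname base_allele_freqs
#' @param m number of earliest-born animals to use.
#' @export
earliest_cohort <- function(g, m) {
  if (m < 1 || m > nrow(g$calls)) stop("invalid base cohort size")
  rownames(g$calls)[order(g$birth_date)][seq_len(m)]
}

#' VanRaden genomic relationship matrix
#'
#' `G = ZZ' / (2 * sum(p_i (1 - p_i)))` with `Z = M - 2p`, where `M` is the
#' dosage matrix and `p` the base-generation allele frequencies (VanRaden
#' method 1).
#'
#' @param g a [genotype_dataset()] with no missing calls.
#' @param p per-SNP base frequencies, e.g. from [base_allele_freqs()].
#' @param exclude_x drop X-linked loci before building the matrix.
#' @return a [relationship_matrix()] of kind `grm_vanraden`.
#' @export
grm_vanraden <- function(g, p, exclude_x = FALSE, x_chrom = "X") {
  if (anyNA(g$calls)) stop("missing calls present; impute first")
  if (length(p) != ncol(g$calls)) stop("freq vector length != number of loci")
  keep <- if (exclude_x) g$map$chrom != x_chrom else rep(TRUE, ncol(g$calls))
  M <- g$calls[, keep, drop = FALSE]
  pk <- p[keep]
  denom <- 2 * sum(pk * (1 - pk))
  if (denom <= 0) stop("zero scaling denominator: all base frequencies fixed")
  Z <- sweep(M, 2L, 2 * pk)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(g$calls), rownames(g$calls))
  relationship_matrix(G, "grm_vanraden", base_freqs = pk)
}

#' @rdname grm_vanraden
#' @param x_chrom X chromosome label.
#' @export
balding_nichols_kinship <- function(g, exclude_x = FALSE, x_chrom = "X") {
  if (anyNA(g$calls)) stop("missing calls present; impute first")
  keep <- if (exclude_x) g$map$chrom != x_chrom else rep(TRUE, ncol(g$calls))
  M <- g$calls[, keep, drop = FALSE]
  p <- colMeans(M) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    stop("monomorphic loci present (run QC first): ",
         paste(head(g$map$snp[keep][mono], 5), collapse = ", "))
  }
  Z <- sweep(M, 2L, 2 * p)
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(g$calls), rownames(g$calls))
  relationship_matrix(K, "balding_nichols", base_freqs = p)
}

#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes per-animal inbreeding coefficients `F` by the Meuwissen-Luo
#' algorithm (the sparse L-row recursion behind the rapid numerator
#' relationship inverse). Founders, and animals with an unknown parent, get
#' `F = 0`.
#'
#' @param ped a [pedigree()]; must be acyclic.
#' @return named numeric vector of class `inbreeding_vector` with attribute
#'   `source = "pedigree"`.
#' @export
pedigree_inbreeding <- function(ped) {
  ord <- pedigree_order(ped)
  ped_s <- ped[ord, , drop = FALSE]
  n <- nrow(ped_s)
  idx <- setNames(seq_len(n), ped_s$animal)
  si <- unname(idx[ped_s$sire]); si[is.na(si)] <- 0L
  di <- unname(idx[ped_s$dam]);  di[is.na(di)] <- 0L
  Fv <- numeric(n)
  Dv <- numeric(n)  # within-family segregation variance for each animal
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Dv[i] <- if (s > 0 && d > 0) 0.5 - 0.25 * (Fv[s] + Fv[d])
             else if (s > 0) 0.75 - 0.25 * Fv[s]
             else if (d > 0) 0.75 - 0.25 * Fv[d]
             else 1
    if (s == 0 || d == 0) { Fv[i] <- 0; next }
    # F_i = 0.5 * A(s, d); compute
    # A(s, d) = sum_j L_sj L_dj D_j by tracing both ancestor rows at once.
    Ls <- numeric(i); Ld <- numeric(i)
    Ls[s] <- 1; Ld[d] <- 1
    a_sd <- 0
    for (j in max(s, d):1) {
      lsj <- Ls[j]; ldj <- Ld[j]
      if (lsj != 0 || ldj != 0) {
        sj <- si[j]; dj <- di[j]
        if (sj > 0) { Ls[sj] <- Ls[sj] + 0.5 * lsj; Ld[sj] <- Ld[sj] + 0.5 * ldj }
        if (dj > 0) { Ls[dj] <- Ls[dj] + 0.5 * lsj; Ld[dj] <- Ld[dj] + 0.5 * ldj }
        a_sd <- a_sd + lsj * ldj * Dv[j]
      }
    }
    Fv[i] <- 0.5 * a_sd
  }
  out <- setNames(numeric(n), ped$animal)
  out[ped_s$animal] <- Fv
  structure(out, source = "pedigree", class = "inbreeding_vector")
}

#' Genomic inbreeding coefficients
#'
#' `F_i = G_ii - 1`, the VanRaden GRM diagonal minus one. Values are
#' referenced to the base-generation allele frequencies and may be negative.
#'
#' @param G a [relationship_matrix()] of kind `grm_vanraden`.
#' @return named numeric vector of class `inbreeding_vector` with attribute
#'   `source = "genomic"`.
#' @export
genomic_inbreeding <- function(G) {
  if (!inherits(G, "relationship_matrix") || G$kind != "grm_vanraden") {
    stop("genomic F is defined on a VanRaden GRM")
  }
  structure(setNames(diag(G$matrix) - 1, rownames(G$matrix)),
            source = "genomic", class = "inbreeding_vector")
}

#' @export
print.inbreeding_vector <- function(x, ...) {
  cat("inbreeding_vector (", attr(x, "source"), "), n = ", length(x), "\n",
      sep = "")
  cat(sprintf("  mean %.4f, var %.6f, range [%.4f, %.4f]\n",
              mean(x), var(as.numeric(x)), min(x), max(x)))
  invisible(x)
}

#' Principal components of a relationship matrix
#'
#' Eigendecomposition of the (centered) relationship matrix; scores are
#' eigenvectors scaled by the square root of their eigenvalues, the standard
#' genotype-PCA projection.
#'
#' @param G a [relationship_matrix()].
#' @param k number of components (positive, less than n).
#' @return list with `scores` (n x k), `values` (non-increasing eigenvalues)
#'   and `prop_var` (fraction of trace per component).
#' @export
grm_principal_components <- function(G, k) {
  A <- if (inherits(G, "relationship_matrix")) G$matrix else G
  n <- nrow(A)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of animals")
  e <- eigen(A, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(scores) <- rownames(A)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, values = e$values, prop_var = vals / sum(vals))
}

#' Write / read a dense relationship matrix as TSV
#' @param G a [relationship_matrix()]
#' @param path TSV path (row/column ids in header and first column)
#' @return `path` invisibly; the reader returns a [relationship_matrix()].
#' @export
write_relationship_matrix <- function(G, path) {
  df <- data.frame(id = rownames(G$matrix), G$matrix, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relationship_matrix
#' @param kind matrix kind, recorded in the returned object.
#' @export
read_relationship_matrix <- function(path, kind = "grm_vanraden") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m <- (m + t(m)) / 2  # remove round-trip asymmetry from printed precision
  relationship_matrix(m, kind)
}

#' Write an inbreeding TSV (id, F_pedigree, F_genomic)
#' @param f_pedigree,f_genomic named `inbreeding_vector`s (either may be NULL)
#' @param path output TSV
#' @return `path`, invisibly.
#' @export
write_inbreeding <- function(path, f_pedigree = NULL, f_genomic = NULL) {
  ids <- union(names(f_pedigree), names(f_genomic))
  pick <- function(f) if (is.null(f)) NA_real_ else as.numeric(f[ids])
  df <- data.frame(id = ids,
                   F_pedigree = pick(f_pedigree),
                   F_genomic = pick(f_genomic))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
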