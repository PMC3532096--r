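#' GBLUP: animal-model mixed-model equations
#'
#' Solves Henderson's mixed-model equations for
#' `y = X beta + g + e`, `g ~ N(0, G sigma2_g)`,
#' `e ~ N(0, sigma2_e * diag(1/w))`, returning fixed-effect estimates and
#' per-animal BLUPs. Weighted records (e.g. deregressed EBVs with Garrick
#' weights) enter through `weights`; with uniform weights the model is the
#' plain animal model used for birth date. A small ridge stabilizes the
#' inverse of `G` when animals outnumber informative markers.
#'
#' @param y numeric response.
#' @param G a [relationship_matrix()] (or plain matrix) for the same animals.
#' @param vc [reml_single_kernel()] variance components (estimated if NULL).
#' @param X fixed-effect design (default: intercept).
#' @param weights positive record weights (default uniform).
#' @param ridge ridge added to the diagonal of `G` before inversion.
#' @return object of class `gblup_fit`: `beta`, `g_hat`, `vc`, `weights`,
#'   plus the inputs needed by [backsolve_snp_effects()].
#' @export
gblup_fit <- function(y, G, vc = NULL, X = NULL, weights = NULL,
                      ridge = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  Gm <- if (inherits(G, "relationship_matrix")) G$matrix else as.matrix(G)
  if (nrow(Gm) != n) stop("G dimension does not match y")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive")
  if (is.null(vc)) vc <- reml_single_kernel(y, Gm, X = X)
  p <- ncol(X)
  Gr <- Gm + diag(ridge, n)

  if (vc$sigma2_g <= 0) {
    # shrinkage limit: g = 0, beta by weighted least squares
    W <- weights
    beta <- solve(crossprod(X, X * W), crossprod(X, y * W))
    ghat <- rep(0, n)
  } else {
    lambda <- vc$sigma2_e / vc$sigma2_g
    Ginv <- tryCatch(solve(Gr), error = function(e)
      stop("singular coefficient matrix; increase `ridge`"))
    D <- weights  # R^-1 * sigma2_e = diag(w)
    C <- rbind(cbind(crossprod(X, X * D), t(X * D)),
               cbind(X * D, diag(D, n) + lambda * Ginv))
    rhs <- c(crossprod(X, y * D), y * D)
    sol <- tryCatch(solve(C, rhs), error = function(e)
      stop("singular coefficient matrix; increase `ridge`"))
    beta <- sol[seq_len(p)]
    ghat <- sol[-seq_len(p)]
  }
  structure(list(beta = as.numeric(beta), g_hat = as.numeric(ghat),
                 vc = vc, weights = weights, ridge = ridge,
                 G = Gm, base_freqs = if (inherits(G, "relationship_matrix"))
                   G$base_freqs else NULL,
                 y = y, X = X),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("gblup_fit:", length(x$g_hat), "animals\n")
  cat("  beta:", paste(signif(x$beta, 4), collapse = ", "), "\n")
  print(x$vc)
  invisible(x)
}

#' Backsolve SNP allele substitution effects from a GBLUP fit
#'
#' Converts animal BLUPs to per-SNP allele substitution effects via
#' `alpha = Z' G^{-1} g_hat / (2 sum p_i (1 - p_i))` with `Z = M - 2p`, the
#' same centering and scaling used to build the GRM. With `G = ZZ'/c` this is
#' algebraically identical to ridge SNP-BLUP at `lambda = c sigma2_e /
#' sigma2_g`. The implied additive variance `2 p (1-p) alpha^2` fills the
#' scan; GBLUP attaches no p-values.
#'
#' @param fit a [gblup_fit()] built on a GRM from these loci and `p`.
#' @param g the [genotype_dataset()] the GRM was built from (no missing
#'   calls).
#' @param p the base allele frequencies used for the GRM (defaults to the
#'   frequencies recorded in the fit's relationship matrix).
#' @return a [scan_result()] ranked by `var_2pqa2` (no p-values).
#' @export
backsolve_snp_effects <- function(fit, g, p = NULL) {
  if (!inherits(fit, "gblup_fit")) stop("fit must be a gblup_fit")
  if (anyNA(g$calls)) stop("missing calls present; impute first")
  p <- p %||% fit$base_freqs
  if (is.null(p)) stop("no base frequencies available; pass `p`")
  if (length(p) != ncol(g$calls)) {
    stop("locus mismatch: fit frequencies cover ", length(p),
         " loci, genotypes have ", ncol(g$calls))
  }
  if (nrow(g$calls) != length(fit$g_hat)) {
    stop("animal mismatch between fit and genotypes")
  }
  denom <- 2 * sum(p * (1 - p))
  Z <- sweep(g$calls, 2L, 2 * p)
  u <- solve(fit$G + diag(fit$ridge, nrow(fit$G)), fit$g_hat)
  alpha <- as.numeric(crossprod(Z, u)) / denom
  scan_result(g$map, freq = p, ase = alpha, rank_by = "variance")
}
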