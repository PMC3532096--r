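#' Single-kernel REML variance components
#'
#' Fits `y = X beta + g + e`, `g ~ N(0, K sigma2_g)`, `e ~ N(0, I sigma2_e)`
#' by restricted maximum likelihood. The kernel is eigendecomposed once and
#' the REML log-likelihood is profiled down to a one-dimensional function of
#' the variance ratio `h2 = sigma2_g / (sigma2_g + sigma2_e)`, which is
#' maximized by Brent search; the fit is exact and deterministic.
#'
#' @param y numeric response (length n >= 3).
#' @param X fixed-effect design matrix (default: intercept only); must have
#'   full column rank.
#' @param K symmetric positive semidefinite kernel (matrix or
#'   [relationship_matrix()]).
#' @param tol convergence tolerance of the Brent search on the ratio.
#' @return object of class `variance_components`: `sigma2_g`, `sigma2_e`,
#'   `ratio`, `loglik` (restricted, up to an additive constant), `n`.
#' @export
reml_single_kernel <- function(y, K, X = NULL, tol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) stop("need at least 3 observations")
  A <- if (inherits(K, "relationship_matrix")) K$matrix else as.matrix(K)
  if (nrow(A) != n) stop("kernel dimension does not match y")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values))) {
    stop("kernel is not positive semidefinite (min eigenvalue ",
         signif(min(e$values), 3), ")")
  }
  d <- pmax(e$values, 0)
  if (max(d) - min(d) < 1e-8 * max(d, 1)) {
    warning("kernel is nearly proportional to the identity; ",
            "the variance ratio is weakly identifiable")
  }
  yt <- crossprod(e$vectors, y)
  Xt <- crossprod(e$vectors, X)
  p <- ncol(X)

  obj <- function(r) reml_ll_rotated(r, yt, Xt, d, n, p)
  opt <- optimize(obj, interval = c(0, 1 - 1e-10), maximum = TRUE, tol = tol)
  # Brent can miss a boundary optimum in (0, tol); check the edges explicitly.
  cand <- c(opt$maximum, 0, 1 - 1e-10)
  ll <- vapply(cand, obj, 0)
  r <- cand[which.max(ll)]
  fit <- reml_ll_rotated(r, yt, Xt, d, n, p, details = TRUE)
  structure(list(sigma2_g = r * fit$sigma2, sigma2_e = (1 - r) * fit$sigma2,
                 ratio = r, loglik = max(ll), n = n),
            class = "variance_components")
}

# Restricted log-likelihood (additive constants dropped) for ratio r, in the
# kernel eigenbasis. v_i = r*d_i + (1-r); sigma2 is profiled out.
reml_ll_rotated <- function(r, yt, Xt, d, n, p, details = FALSE) {
  v <- r * d + (1 - r)
  if (any(v <= 0)) return(if (details) list(sigma2 = NA) else -Inf)
  w <- 1 / v
  XtWX <- crossprod(Xt, Xt * w)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(if (details) list(sigma2 = NA) else -Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, yt * w)))
  res <- yt - Xt %*% beta
  rss <- sum(res^2 * w)
  sigma2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma2) + sum(log(v)) +
                  2 * sum(log(diag(ch))) + (n - p))
  if (details) list(sigma2 = sigma2, beta = beta, ll = ll) else ll
}

#' REML profile log-likelihood over a grid of variance ratios
#'
#' Diagnostic companion to [reml_single_kernel()]: evaluates the profiled
#' restricted log-likelihood at user-supplied ratios (same parametrization
#' and constant as the optimizer), e.g. to inspect flat likelihoods.
#'
#' @inheritParams reml_single_kernel
#' @param ratios vector of variance ratios in `[0, 1)`.
#' @return data.frame with columns `ratio`, `loglik`.
#' @export
reml_profile <- function(y, K, X = NULL, ratios = seq(0, 0.99, length.out = 100)) {
  y <- as.numeric(y); n <- length(y)
  A <- if (inherits(K, "relationship_matrix")) K$matrix else as.matrix(K)
  if (is.null(X)) X <- matrix(1, n, 1)
  e <- eigen(A, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yt <- crossprod(e$vectors, y)
  Xt <- crossprod(e$vectors, X)
  data.frame(ratio = ratios,
             loglik = vapply(ratios, reml_ll_rotated, 0, yt = yt, Xt = Xt,
                             d = d, n = n, p = ncol(X)))
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components: sigma2_g = %.4g, sigma2_e = %.4g, ratio = %.4f (n = %d)\n",
              x$sigma2_g, x$sigma2_e, x$ratio, x$n))
  invisible(x)
}
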