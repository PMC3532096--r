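#' Deregress estimated breeding values
#'
#' Removes the shrinkage applied in genetic evaluation so that EBVs can be
#' re-analysed as pseudo-phenotypes with information-content weights.
#'
#' `mode = "simple"` (default): `dEBV = EBV / r2` with weight
#' `w = (1 - h2) / ((c + (1 - r2) / r2) * h2)`, where `r2` is the EBV
#' reliability, `h2` the trait heritability and `c` the fraction of genetic
#' variance not captured by the markers. As `r2 -> 1` with `c = 0` the weight
#' diverges; it is capped at `weight_max` with a warning.
#'
#' `mode = "parent_adjusted"` additionally strips the parent-average
#' contribution given sire/dam EBVs and reliabilities (Garrick-style
#' two-equation system); it requires `ebv_sire`, `ebv_dam`, `r2_sire`,
#' `r2_dam` and returns the deregressed individual information with its
#' effective reliability.
#'
#' @param ebv estimated breeding value(s), trait units.
#' @param r2 reliability of the EBV, in (0, 1].
#' @param h2 trait heritability, in (0, 1].
#' @param c fraction of genetic variance not explained by markers, in
#'   `[0, 1)`.
#' @param mode `"simple"` or `"parent_adjusted"`.
#' @param ebv_sire,ebv_dam,r2_sire,r2_dam parent information for
#'   `parent_adjusted` mode.
#' @param weight_max cap applied to diverging weights.
#' @return data.frame of class `deregressed_record` with columns `debv`,
#'   `weight`, `accuracy_r2` (the reliability attributed to the deregressed
#'   record) and `c`.
#' @export
deregress_ebv <- function(ebv, r2, h2, c, mode = c("simple", "parent_adjusted"),
                          ebv_sire = NULL, ebv_dam = NULL,
                          r2_sire = NULL, r2_dam = NULL,
                          weight_max = 1e6) {
  mode <- match.arg(mode)
  k <- max(length(ebv), length(r2))
  ebv <- rep_len(ebv, k); r2 <- rep_len(r2, k)
  if (any(r2 <= 0)) stop("no information to deregress: r2 must be > 0")
  if (any(r2 > 1)) stop("r2 must lie in (0, 1]")
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must lie in (0, 1]")
  if (any(c < 0 | c >= 1)) stop("c must lie in [0, 1)")

  if (mode == "simple") {
    debv <- ebv / r2
    r2_eff <- r2
  } else {
    for (nm in list(ebv_sire, ebv_dam, r2_sire, r2_dam)) {
      if (is.null(nm)) stop("parent_adjusted mode needs parent EBVs and reliabilities")
    }
    ebv_sire <- rep_len(ebv_sire, k); ebv_dam <- rep_len(ebv_dam, k)
    r2_sire <- rep_len(r2_sire, k); r2_dam <- rep_len(r2_dam, k)
    lambda <- (1 - h2) / h2
    r2pa <- (r2_sire + r2_dam) / 4
    ebv_pa <- (ebv_sire + ebv_dam) / 2
    # effective record contents of the parent-average and individual sources
    alpha <- 1 / (0.5 - r2pa)
    delta <- (0.5 - r2pa) / (1 - r2)
    ZpZpa <- lambda * (0.5 * alpha - 4) + 0.5 * lambda *
      sqrt(alpha^2 + 16 / delta)
    ZpZi <- delta * ZpZpa + 2 * lambda * (2 * delta - 1)
    ZpZi <- pmax(ZpZi, 1e-12)
    debv <- (-2 * lambda * ebv_pa + (ZpZi + 2 * lambda) * ebv) / ZpZi
    r2_eff <- 1 - lambda / (ZpZi + lambda)
    r2_eff <- pmin(pmax(r2_eff, 1e-8), 1)
  }
  w <- (1 - h2) / ((c + (1 - r2_eff) / r2_eff) * h2)
  over <- !is.finite(w) | w > weight_max
  if (any(over)) {
    warning(sum(over), " weight(s) exceeded weight_max (fully reliable ",
            "record with c = 0); capped at ", weight_max)
    w[over] <- weight_max
  }
  if (any(!is.finite(debv))) stop("non-finite deregressed value produced")
  out <- data.frame(debv = debv, weight = w, accuracy_r2 = r2_eff,
                    c = rep_len(c, k))
  class(out) <- c("deregressed_record", "data.frame")
  out
}
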