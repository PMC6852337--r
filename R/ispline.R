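#' M-spline basis
#'
#' M-splines of a given order on a knot vector: non-negative piecewise
#' polynomials, each integrating to one over the knot range. The basis
#' holds `length(knots) + order - 2` functions. Used as the densities whose
#' running integrals form the monotone I-splines of the dissimilarity
#' models.
#'
#' @param x evaluation points (clamped to the knot range).
#' @param knots strictly increasing knot vector (>= 2 distinct values).
#' @param order M-spline order (polynomial degree + 1); default 2 gives
#'   piecewise-linear M-splines and quadratic I-splines.
#' @return matrix `length(x)` x n_basis.
#' @export
mspline_basis <- function(x, knots, order = 2) {
  check_knots(knots)
  k <- order
  aug <- c(rep(knots[1], k), knots[-c(1, length(knots))],
           rep(knots[length(knots)], k))
  x <- pmin(pmax(x, knots[1]), knots[length(knots)])
  # splineDesign is right-open; nudge points at the right boundary inside
  xr <- pmin(x, knots[length(knots)] - 1e-12 * diff(range(knots)))
  B <- splines::splineDesign(aug, xr, ord = k)
  n_basis <- length(aug) - k
  norm <- k / (aug[seq_len(n_basis) + k] - aug[seq_len(n_basis)])
  sweep(B, 2, norm, `*`)
}

#' I-spline basis
#'
#' Monotone non-decreasing spline basis: each I-spline is the running
#' integral of the corresponding M-spline, so it is 0 at the lower knot and
#' 1 at the upper knot; evaluation outside the knot range is clamped. A
#' non-negative combination of I-splines is therefore a monotone link
#' between a predictor and compositional turnover.
#'
#' @inheritParams mspline_basis
#' @return matrix `length(x)` x n_basis with values in `[0, 1]`.
#' @export
ispline_basis <- function(x, knots, order = 2) {
  check_knots(knots)
  k <- order
  # I-splines via B-splines one order up: I_i(x) = sum_{j > i} B_j(x)
  aug <- c(rep(knots[1], k + 1), knots[-c(1, length(knots))],
           rep(knots[length(knots)], k + 1))
  x <- pmin(pmax(x, knots[1]), knots[length(knots)])
  at_top <- x >= knots[length(knots)]
  xr <- pmin(x, knots[length(knots)] - 1e-12 * diff(range(knots)))
  B <- splines::splineDesign(aug, xr, ord = k + 1)
  nb <- ncol(B)
  I <- t(apply(B, 1, function(row) rev(cumsum(rev(row)))))[, -1, drop = FALSE]
  I[at_top, ] <- 1 # exact at the upper knot
  I[I > 1] <- 1; I[I < 0] <- 0
  I
}

check_knots <- function(knots) {
  if (length(knots) < 2 || any(diff(knots) <= 0))
    stop("knots must contain at least 2 strictly increasing values")
  invisible(knots)
}

# Default GDM knots: quantiles of the pooled predictor values at the
# 0/50/100th percentiles (n_splines evenly spaced probabilities). When the
# quantiles tie (heavily skewed or few-valued predictors, e.g. factor
# contrasts) fall back to evenly spaced knots over the range; a predictor
# with no spread at all is degenerate and the caller drops it.
gdm_knots <- function(values, n_splines = 3) {
  rng <- range(values, na.rm = TRUE)
  if (diff(rng) <= 0) return(NULL)
  q <- unname(stats::quantile(values, probs = seq(0, 1,
                                                  length.out = n_splines),
                              na.rm = TRUE, type = 7))
  if (any(diff(q) <= 0)) q <- seq(rng[1], rng[2], length.out = n_splines)
  q
}
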