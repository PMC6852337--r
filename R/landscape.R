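#' Stationary Gaussian random field on a grid
#'
#' Simulates a zero-mean, unit-variance Gaussian random field with an
#' exponential correlation function by circulant embedding on the torus
#' (FFT spectral synthesis). `range` is the practical range: the lag (in
#' cells) at which correlation has decayed to 0.05, i.e. the semivariogram
#' has reached 95% of its sill.
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param range practical correlation range in cells.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `nrow` x `ncol` numeric matrix.
#' @export
gaussian_random_field <- function(nrow, ncol, range, seed = NULL) {
  stopifnot(nrow >= 2, ncol >= 2, range > 0)
  with_seed(seed, {
    dx <- pmin(0:(ncol - 1), ncol - 0:(ncol - 1))
    dy <- pmin(0:(nrow - 1), nrow - 0:(nrow - 1))
    d <- sqrt(outer(dy^2, dx^2, `+`))
    C <- exp(-3 * d / range)
    S <- Re(stats::fft(C))
    S[S < 0] <- 0 # embedding can leak tiny negatives; clip
    eps <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
    f <- stats::fft(sqrt(S) * stats::fft(eps), inverse = TRUE) / (nrow * ncol)
    Re(f)
  })
}

#' Generate a synthetic landscape
#'
#' Builds the arena used throughout the workflow: a categorical forest-type
#' raster, a per-cell density raster, and spatially autocorrelated
#' environmental covariates (elevation and top-of-canopy height), all on a
#' common grid of square cells. Forest types are obtained by thresholding a
#' seeded Gaussian random field at equal-area quantiles, which yields
#' contiguous-tending mosaics like real floristic associations; a
#' deterministic `"bands"` pattern of vertical stripes is also available for
#' controlled experiments.
#'
#' @param width,height grid dimensions in cells (>= 2).
#' @param n_types number of forest types (>= 1).
#' @param autocorr_range practical autocorrelation range of the covariate
#'   fields, in cells.
#' @param cell_size cell edge length in metres (default 100, i.e. 1-ha cells).
#' @param density individuals per cell (positive integer, recycled to a
#'   raster).
#' @param elev_range,tch_range min/max used to rescale the elevation and
#'   canopy-height fields (metres).
#' @param type_pattern `"field"` (thresholded random field) or `"bands"`
#'   (vertical stripes of equal width).
#' @param seed integer seed; the same seed reproduces the landscape exactly.
#' @return an object of class `landscape`: list with `width`, `height`,
#'   `cell_size`, `forest_type` (integer matrix, `height` x `width`),
#'   `density` (integer matrix), `covariates` (named list of matrices) and
#'   `origin`.
#' @export
gen_landscape <- function(width, height, n_types = 3, autocorr_range = 20,
                          cell_size = 100, density = 1,
                          elev_range = c(0, 120), tch_range = c(10, 60),
                          type_pattern = c("field", "bands"), seed = 1) {
  if (width < 2 || height < 2) stop("landscape dimensions must be >= 2 cells")
  if (n_types < 1) stop("n_types must be >= 1")
  if (n_types > width * height) stop("n_types exceeds the number of cells")
  type_pattern <- match.arg(type_pattern)
  if (any(density < 1)) stop("density must be >= 1 everywhere")

  covs <- with_seed(seed, list(
    elevation = rescale_range(
      gaussian_random_field(height, width, autocorr_range), elev_range),
    tch = rescale_range(
      gaussian_random_field(height, width, autocorr_range), tch_range)
  ))
  forest_type <- if (n_types == 1) {
    matrix(1L, height, width)
  } else if (type_pattern == "bands") {
    matrix(rep(as.integer(cut(seq_len(width), n_types, labels = FALSE)),
               each = height), height, width)
  } else {
    f <- with_seed(child_seed(seed, 3L),
                   gaussian_random_field(height, width, autocorr_range))
    q <- stats::quantile(f, probs = seq(0, 1, length.out = n_types + 1))
    q[1] <- -Inf; q[n_types + 1] <- Inf
    matrix(as.integer(cut(f, breaks = q, labels = FALSE)), height, width)
  }
  dens <- matrix(as.integer(density), height, width)

  structure(
    list(width = as.integer(width), height = as.integer(height),
         cell_size = cell_size, n_types = as.integer(n_types),
         forest_type = forest_type, density = dens, covariates = covs,
         origin = c(0, 0), autocorr_range = autocorr_range, seed = seed),
    class = "landscape")
}

#' Cell-centre coordinates of a landscape
#'
#' @param landscape a [gen_landscape()] object.
#' @return a matrix with columns `x`, `y` in metres, one row per cell in
#'   column-major (raster) order.
#' @export
cell_centres <- function(landscape) {
  cs <- landscape$cell_size
  x <- landscape$origin[1] + (seq_len(landscape$width) - 0.5) * cs
  y <- landscape$origin[2] + (seq_len(landscape$height) - 0.5) * cs
  cbind(x = rep(x, each = landscape$height),
        y = rep(y, times = landscape$width))
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", x$width, "x", x$height, " cells of ", x$cell_size,
      " m, ", x$n_types, " forest type(s)\n", sep = "")
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}
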