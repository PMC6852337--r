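# Terrain descriptors computed on elevation rasters (matrices). All three
# metrics shrink the 3x3 neighbourhood at raster edges rather than padding,
# so no elevations are fabricated outside the data.

# Stack the 8 neighbour shifts of a matrix as an nrow*ncol x 8 matrix with
# NA where the neighbour falls outside the raster.
neighbour_stack <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  out <- matrix(NA_real_, nr * nc, 8)
  for (s in seq_len(8)) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    src_r <- seq_len(nr) + dr
    src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    m <- matrix(NA_real_, nr, nc)
    m[ok_r, ok_c] <- z[src_r[ok_r], src_c[ok_c]]
    out[, s] <- as.vector(m)
  }
  out
}

#' Terrain ruggedness index (TRI)
#'
#' For each cell, the square root of the mean squared elevation difference
#' between the cell and its eight neighbours. Edge cells use the neighbours
#' available to them.
#'
#' @param z elevation raster (matrix, >= 3x3).
#' @return TRI raster (same shape, metres).
#' @export
terrain_tri <- function(z) {
  stopifnot(nrow(z) >= 3, ncol(z) >= 3)
  nb <- neighbour_stack(z)
  d2 <- (as.vector(z) - nb)^2
  matrix(sqrt(rowMeans(d2, na.rm = TRUE)), nrow(z), ncol(z))
}

#' Topographic position index (TPI)
#'
#' Elevation of each cell minus the mean of its eight neighbours: positive
#' on hilltops and ridges, negative in valleys, zero on planes. Edge cells
#' use the neighbours available to them.
#'
#' @param z elevation raster (matrix, >= 3x3).
#' @return TPI raster (metres).
#' @export
terrain_tpi <- function(z) {
  stopifnot(nrow(z) >= 3, ncol(z) >= 3)
  nb <- neighbour_stack(z)
  matrix(as.vector(z) - rowMeans(nb, na.rm = TRUE), nrow(z), ncol(z))
}

#' Terrain slope in degrees (Horn stencil)
#'
#' Slope from 3x3 central differences with Horn's weights: the row/column
#' gradients are (weighted) central differences over the neighbouring
#' cells, and slope = atan(|gradient|) in degrees. Edge gradients use the
#' available one-sided differences.
#'
#' @param z elevation raster (matrix, >= 3x3).
#' @param cell_size cell edge length in metres.
#' @return slope raster in degrees.
#' @export
terrain_slope <- function(z, cell_size = 1) {
  stopifnot(nrow(z) >= 3, ncol(z) >= 3, cell_size > 0)
  nr <- nrow(z); nc <- ncol(z)
  # pad by edge replication so Horn's stencil degenerates to one-sided
  # differences at the borders
  zp <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  dzdx <- ((zp[ri - 1, ci + 1] + 2 * zp[ri, ci + 1] + zp[ri + 1, ci + 1]) -
             (zp[ri - 1, ci - 1] + 2 * zp[ri, ci - 1] + zp[ri + 1, ci - 1])) /
    (8 * cell_size)
  dzdy <- ((zp[ri + 1, ci - 1] + 2 * zp[ri + 1, ci] + zp[ri + 1, ci + 1]) -
             (zp[ri - 1, ci - 1] + 2 * zp[ri - 1, ci] + zp[ri - 1, ci + 1])) /
    (8 * cell_size)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

#' Aggregate pixel rasters to cell means
#'
#' @param z pixel raster (matrix).
#' @param px_per_cell pixels per cell edge.
#' @return matrix of per-cell means (trailing partial cells averaged over
#'   their available pixels).
#' @export
aggregate_cells <- function(z, px_per_cell) {
  stopifnot(px_per_cell >= 1)
  ri <- (seq_len(nrow(z)) - 1L) %/% px_per_cell
  ci <- (seq_len(ncol(z)) - 1L) %/% px_per_cell
  rowsum_r <- rowsum(z, ri)
  n_r <- as.vector(table(ri))
  m <- rowsum(t(rowsum_r / n_r), ci)
  n_c <- as.vector(table(ci))
  t(m / n_c)
}

#' Per-cell environmental descriptor table
#'
#' Computes the environmental predictors used in the dissimilarity models
#' for every cell of a landscape: mean elevation, slope, topographic
#' ruggedness (TRI), topographic position (TPI), mean top-of-canopy height
#' (TCH) and forest type. Metrics are computed on the cell-resolution
#' elevation raster (cell spacing = `landscape$cell_size`).
#'
#' @param landscape a [gen_landscape()] object.
#' @return data.frame with one row per cell in [cell_centres()] order:
#'   `cell`, `x`, `y`, `elevation`, `slope`, `tri`, `tpi`, `tch`,
#'   `forest_type` (factor).
#' @export
cell_environment <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  z <- landscape$covariates$elevation
  cc <- cell_centres(landscape)
  data.frame(
    cell = paste0("s", seq_len(nrow(cc))),
    x = cc[, "x"], y = cc[, "y"],
    elevation = as.vector(z),
    slope = as.vector(terrain_slope(z, landscape$cell_size)),
    tri = as.vector(terrain_tri(z)),
    tpi = as.vector(terrain_tpi(z)),
    tch = as.vector(landscape$covariates$tch),
    forest_type = factor(as.vector(landscape$forest_type),
                         levels = seq_len(landscape$n_types)))
}
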