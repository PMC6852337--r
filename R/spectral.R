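#' Quality-filter the pixels of a reflectance cube
#'
#' Applies the image quality checks run after atmospheric correction: pixels
#' with NDVI below `ndvi_threshold` are discarded (low forest cover), pixels
#' illuminated at solar zenith angles above `zenith_max` are removed, and
#' pixels with non-finite spectra are dropped. NDVI is computed from the
#' bands nearest 660 nm (red) and 800 nm (NIR).
#'
#' @param cube a [gen_cube()]-style `reflectance_cube` (or any list with
#'   `reflectance`, `wavelengths`, `zenith`).
#' @param ndvi_threshold minimum NDVI retained (default 0.8).
#' @param zenith_max maximum solar zenith angle retained, degrees
#'   (default 50).
#' @return an object of class `pixel_mask`: logical `mask` raster (TRUE =
#'   pixel passes all filters), per-filter failure `counts`, and the `ndvi`
#'   raster.
#' @export
filter_pixels <- function(cube, ndvi_threshold = 0.8, zenith_max = 50) {
  wl <- cube$wavelengths
  if (min(wl) > 660 || max(wl) < 800)
    stop("cube wavelengths do not bracket the red (660 nm) and NIR (800 nm) bands")
  red_b <- which.min(abs(wl - 660))
  nir_b <- which.min(abs(wl - 800))
  red <- cube$reflectance[, , red_b]
  nir <- cube$reflectance[, , nir_b]
  ndvi <- (nir - red) / (nir + red)
  ndvi[!is.finite(ndvi)] <- 0

  d <- dim(cube$reflectance)
  finite <- matrix(rowSums(!is.finite(matrix(cube$reflectance,
                                             d[1] * d[2], d[3]))) == 0,
                   d[1], d[2])
  fail_ndvi <- ndvi < ndvi_threshold
  fail_zen <- cube$zenith > zenith_max
  mask <- finite & !fail_ndvi & !fail_zen
  counts <- c(n_total = length(mask), n_nonfinite = sum(!finite),
              n_ndvi_fail = sum(fail_ndvi), n_zenith_fail = sum(fail_zen),
              n_pass = sum(mask))
  structure(list(mask = mask, counts = counts, ndvi = ndvi,
                 ndvi_threshold = ndvi_threshold, zenith_max = zenith_max),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat("<pixel_mask> ", x$counts["n_pass"], "/", x$counts["n_total"],
      " pixels pass (NDVI >= ", x$ndvi_threshold, ", zenith <= ",
      x$zenith_max, " deg)\n", sep = "")
  invisible(x)
}

#' Brightness-normalise spectra
#'
#' Divides each spectrum by its Euclidean (L2) norm so all pixels lie on the
#' unit sphere, removing albedo/illumination brightness differences while
#' preserving spectral shape.
#'
#' @param x a numeric vector (one spectrum) or matrix (pixels in rows).
#' @return the normalised vector or matrix; every row has unit norm.
#' @export
brightness_normalise <- function(x) {
  if (is.matrix(x)) {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0))
      stop("all-zero spectrum in row(s) ",
           paste(utils::head(which(nrm == 0), 5), collapse = ", "),
           "; drop before normalising")
    return(x / nrm)
  }
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot brightness-normalise an all-zero spectrum")
  x / nrm
}

#' Spectrally resample a cube
#'
#' Removes the low signal-to-noise sensor extremes (below `min_wl`, above
#' `max_wl`) and the atmospheric water absorption windows, then averages the
#' remaining bands in consecutive non-overlapping groups -- `vnir_group`
#' bands at a time in the visible/near-infrared (wavelength <= `vnir_max`)
#' and `swir_group` bands at a time in the shortwave infrared. A trailing
#' incomplete group is averaged over its available members.
#'
#' @param cube a `reflectance_cube`.
#' @param vnir_group,swir_group group sizes (defaults 3 and 2).
#' @param min_wl,max_wl retained wavelength limits in nm (420 and 2400).
#' @param water_bands list of inclusive wavelength ranges to drop.
#' @param vnir_max boundary between the VNIR and SWIR regions (nm).
#' @return a `reflectance_cube` with the reduced band set.
#' @export
resample_bands <- function(cube, vnir_group = 3, swir_group = 2,
                           min_wl = 420, max_wl = 2400,
                           water_bands = list(c(1350, 1480), c(1780, 2032)),
                           vnir_max = 1000) {
  wl <- cube$wavelengths
  drop <- wl < min_wl | wl > max_wl
  for (rng in water_bands) drop <- drop | (wl >= rng[1] & wl <= rng[2])
  keep <- which(!drop)
  if (!length(keep)) stop("no bands remain after exclusion")

  wl_keep <- wl[keep]
  grp <- integer(length(keep))
  vnir <- wl_keep <= vnir_max
  if (any(vnir)) grp[vnir] <- (seq_len(sum(vnir)) - 1L) %/% vnir_group
  if (any(!vnir))
    grp[!vnir] <- max(grp[vnir], -1L) + 1L +
      (seq_len(sum(!vnir)) - 1L) %/% swir_group
  d <- dim(cube$reflectance)
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])[, keep, drop = FALSE]
  groups <- split(seq_along(keep), grp)
  new_flat <- vapply(groups, function(ix) rowMeans(flat[, ix, drop = FALSE]),
                     numeric(nrow(flat)))
  new_wl <- vapply(groups, function(ix) mean(wl_keep[ix]), numeric(1))
  out <- cube
  out$reflectance <- array(new_flat, dim = c(d[1], d[2], length(groups)))
  out$wavelengths <- unname(new_wl)
  out
}

#' Cluster pixel spectra into spectral species
#'
#' Groups (masked, brightness-normalised) pixel spectra into `k` clusters by
#' k-means; each cluster is subsequently treated as a proxy taxon
#' ("spectral species") when computing compositional dissimilarity. The
#' full-batch path runs seeded Lloyd iterations via [stats::kmeans()]; the
#' `"minibatch"` method implements the mini-batch variant (per-centroid
#' learning rates over random batches) for large scenes.
#'
#' @param x pixels x bands numeric matrix.
#' @param k number of clusters (`k <= nrow(x)`).
#' @param seed integer seed; fits are deterministic given the seed.
#' @param method `"lloyd"` (full batch) or `"minibatch"`.
#' @param batch_size mini-batch size.
#' @param iter maximum iterations.
#' @param nstart random restarts for the full-batch path (best fit kept).
#' @return an object of class `cluster_model` with `centroids` (k x bands),
#'   `k`, total within-cluster sum of squares `wss`, `seed` and `method`.
#' @export
fit_clusters <- function(x, k, seed = 1, method = c("lloyd", "minibatch"),
                         batch_size = 1024, iter = 100, nstart = 1) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k = ", k, " exceeds the pixel count ", nrow(x))
  with_seed(seed, {
    if (method == "lloyd") {
      km <- suppressWarnings(
        stats::kmeans(x, centers = k, algorithm = "Lloyd",
                      iter.max = iter, nstart = nstart))
      centroids <- km$centers
    } else {
      centroids <- x[sample.int(nrow(x), k), , drop = FALSE]
      n_seen <- rep(0, k)
      for (i in seq_len(iter)) {
        batch <- x[sample.int(nrow(x), min(batch_size, nrow(x))), ,
                   drop = FALSE]
        a <- nearest_centroid(batch, centroids)
        for (c_id in unique(a)) {
          rows <- which(a == c_id)
          for (r in rows) {
            n_seen[c_id] <- n_seen[c_id] + 1
            eta <- 1 / n_seen[c_id]
            centroids[c_id, ] <- (1 - eta) * centroids[c_id, ] +
              eta * batch[r, ]
          }
        }
      }
    }
    assign <- nearest_centroid(x, centroids)
    wss <- sum((x - centroids[assign, , drop = FALSE])^2)
    structure(list(k = k, centroids = unname(as.matrix(centroids)),
                   wss = wss, seed = seed, method = method),
              class = "cluster_model")
  })
}

# Index of the nearest centroid per row (Euclidean); ties go to the lowest
# cluster id because max.col/which.min take the first minimum.
nearest_centroid <- function(x, centroids) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) -
    2 * x %*% t(centroids) +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
  max.col(-d2, ties.method = "first")
}

#' Assign pixels to fitted spectral clusters
#'
#' @param model a [fit_clusters()] model.
#' @param x pixels x bands matrix on the same band set.
#' @return integer vector of cluster ids (nearest centroid, ties to the
#'   lowest id).
#' @export
assign_clusters <- function(model, x) {
  nearest_centroid(as.matrix(x), model$centroids)
}

#' Within-cluster sum of squares across a grid of k
#'
#' Fits k-means over `k_grid` and reports the mean within-cluster sum of
#' squares for each k, flagging the elbow (largest second difference of
#' log WSS) as a suggestion for the cluster count.
#'
#' @param x pixels x bands matrix.
#' @param k_grid increasing vector of candidate k.
#' @param seed integer seed.
#' @param ... passed to [fit_clusters()].
#' @return data.frame with columns `k`, `wss`, `mean_wss`; the suggested
#'   elbow is in `attr(, "knee")` (NA when the grid is too short).
#' @export
select_k <- function(x, k_grid, seed = 1, ...) {
  if (is.unsorted(k_grid, strictly = TRUE))
    stop("k_grid must be sorted strictly ascending")
  fits <- lapply(seq_along(k_grid), function(i)
    fit_clusters(x, k_grid[i], seed = child_seed(seed, i), ...))
  wss <- vapply(fits, `[[`, numeric(1), "wss")
  out <- data.frame(k = k_grid, wss = wss, mean_wss = wss / nrow(x))
  knee <- NA_integer_
  if (length(k_grid) >= 3) {
    d2 <- diff(diff(log(pmax(wss, 1e-12))))
    knee <- k_grid[which.max(d2) + 1L]
  }
  attr(out, "knee") <- knee
  out
}

#' Grid cluster abundances into a community matrix
#'
#' Overlays a virtual grid of square cells on a cluster-id raster and counts
#' the pixels of each cluster in each cell; cells whose fraction of valid
#' (unmasked) pixels falls below `min_coverage` are dropped and reported.
#'
#' @param clusters integer raster (matrix) of cluster ids with `NA` at
#'   masked pixels.
#' @param pixel_size pixel edge length in metres.
#' @param cell_size cell edge length in metres (default 100 = 1 ha).
#' @param min_coverage minimum valid-pixel fraction retained (default 0.25).
#' @param k number of clusters (defaults to the maximum id present).
#' @param origin coordinates of the raster's lower-left corner.
#' @return a [community_matrix()]; dropped cell ids are in
#'   `attr(, "dropped")`.
#' @export
grid_abundances <- function(clusters, pixel_size, cell_size = 100,
                            min_coverage = 0.25, k = NULL, origin = c(0, 0)) {
  if (cell_size < pixel_size)
    stop("cell_size must be at least the pixel size")
  ppc <- cell_size / pixel_size
  if (abs(ppc - round(ppc)) > 1e-8)
    stop("cell_size must be an integer multiple of pixel_size")
  ppc <- as.integer(round(ppc))
  k <- k %||% max(clusters, na.rm = TRUE)
  counts <- pixel_counts_per_cell(clusters, ppc, k)
  colnames(counts) <- paste0("cluster_", seq_len(k))
  ch <- ceiling(nrow(clusters) / ppc); cw <- ceiling(ncol(clusters) / ppc)
  coords <- cbind(
    x = origin[1] + (rep(seq_len(cw), each = ch) - 0.5) * cell_size,
    y = origin[2] + (rep(seq_len(ch), times = cw) - 0.5) * cell_size)
  coverage <- rowSums(counts) / ppc^2
  keep <- coverage >= min_coverage
  ids <- paste0("cell_", seq_len(ch * cw))
  out <- community_matrix(counts[keep, , drop = FALSE],
                          coords[keep, , drop = FALSE],
                          coverage = coverage[keep], ids = ids[keep])
  attr(out, "dropped") <- ids[!keep]
  out
}

#' Run the full spectral beta-diversity chain on a cube
#'
#' Convenience wrapper for the image-to-community pipeline: quality filter,
#' spectral resampling, brightness normalisation, k-means spectral species,
#' and gridding of cluster abundances into 1-ha (by default) cells.
#'
#' @param cube a `reflectance_cube`.
#' @param k number of spectral species.
#' @param seed integer seed for the clustering.
#' @param ndvi_threshold,zenith_max quality-filter settings
#'   (see [filter_pixels()]).
#' @param cell_size,min_coverage gridding settings (see
#'   [grid_abundances()]).
#' @param resample apply [resample_bands()] first (default TRUE).
#' @param ... further arguments to [fit_clusters()].
#' @return list with the gridded `community` ([community_matrix()]), the
#'   `model` ([fit_clusters()]), the `mask` ([filter_pixels()]) and the
#'   `cluster_raster` (NA outside the mask).
#' @export
spectral_species <- function(cube, k, seed = 1, ndvi_threshold = 0.8,
                             zenith_max = 50, cell_size = 100,
                             min_coverage = 0.25, resample = TRUE, ...) {
  mask <- filter_pixels(cube, ndvi_threshold, zenith_max)
  work <- if (resample) resample_bands(cube) else cube
  d <- dim(work$reflectance)
  flat <- matrix(work$reflectance, d[1] * d[2], d[3])
  ok <- as.vector(mask$mask) & sqrt(rowSums(flat^2)) > 0
  norm <- brightness_normalise(flat[ok, , drop = FALSE])
  model <- fit_clusters(norm, k, seed = seed, ...)
  raster <- matrix(NA_integer_, d[1], d[2])
  raster[ok] <- assign_clusters(model, norm)
  community <- grid_abundances(raster, pixel_size = cube$pixel_size,
                               cell_size = cell_size,
                               min_coverage = min_coverage, k = k)
  list(community = community, model = model, mask = mask,
       cluster_raster = raster)
}
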