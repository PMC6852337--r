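#' Generate a synthetic community with known niche and dispersal structure
#'
#' Assigns one canopy individual (species id) to every pixel of a fine grid
#' overlaid on a [gen_landscape()] arena. Each species receives a forest-type
#' affinity and an elevation optimum; per-pixel assignment probabilities are
#' proportional to `exp(niche_strength * suitability)` multiplied by a
#' Thomas-process-like patch intensity (`1 + aggregation * patch field`,
#' Gaussian bumps around seeded parent points) that emulates dispersal
#' clustering. With `niche_strength = 0` and `aggregation = 0` the assignment
#' is i.i.d. uniform over species.
#'
#' @param landscape a [gen_landscape()] object.
#' @param n_species number of species (>= 1).
#' @param niche_strength non-negative strength of environmental filtering.
#' @param aggregation non-negative strength of dispersal clustering.
#' @param px_per_cell pixels per cell edge (pixel grid is
#'   `height*px_per_cell` x `width*px_per_cell`).
#' @param patches_per_species parent points per species for the patch field.
#' @param seed integer seed.
#' @return an object of class `synthetic_truth`: the per-pixel species raster,
#'   the per-cell true [community_matrix()], and the generating parameters.
#' @export
gen_community <- function(landscape, n_species, niche_strength = 0,
                          aggregation = 0, px_per_cell = 5,
                          patches_per_species = 8, seed = 1) {
  stopifnot(inherits(landscape, "landscape"), n_species >= 1,
            niche_strength >= 0, aggregation >= 0, px_per_cell >= 1)
  pr <- landscape$height * px_per_cell
  pc <- landscape$width * px_per_cell
  npx <- pr * pc

  # upsample cell-level covariates/types to the pixel grid
  rows_up <- rep(seq_len(landscape$height), each = px_per_cell)
  cols_up <- rep(seq_len(landscape$width), each = px_per_cell)
  elev_px <- landscape$covariates$elevation[rows_up, cols_up, drop = FALSE]
  type_px <- landscape$forest_type[rows_up, cols_up, drop = FALSE]

  with_seed(seed, {
    affinity <- sample.int(landscape$n_types, n_species, replace = TRUE)
    er <- range(elev_px)
    optimum <- stats::runif(n_species, er[1], er[2])
    bw <- max(0.15 * diff(er), 1e-6)

    px_row <- rep(seq_len(pr), times = pc)
    px_col <- rep(seq_len(pc), each = pr)
    logw <- matrix(0, npx, n_species)
    patch_scale <- 2 * px_per_cell
    for (s in seq_len(n_species)) {
      # the forest-type match outweighs the (bounded) elevation term, so
      # large niche_strength makes affinities effectively type-exclusive
      suit <- 2 * (as.numeric(type_px) == affinity[s]) +
        exp(-(as.numeric(elev_px) - optimum[s])^2 / (2 * bw^2))
      w <- exp(niche_strength * suit)
      if (aggregation > 0) {
        pry <- stats::runif(patches_per_species, 0.5, pr + 0.5)
        prx <- stats::runif(patches_per_species, 0.5, pc + 0.5)
        d2 <- outer(px_row, pry, `-`)^2 + outer(px_col, prx, `-`)^2
        patch <- rowSums(exp(-d2 / (2 * patch_scale^2)))
        patch <- patch / max(patch)
        w <- w * (1 + aggregation * patch)
      }
      logw[, s] <- log(w)
    }
    # Gumbel-max trick: one categorical draw per pixel, vectorised
    g <- -log(-log(matrix(stats::runif(npx * n_species), npx, n_species)))
    sp <- max.col(logw + g, ties.method = "first")
    species_raster <- matrix(sp, pr, pc)

    counts <- pixel_counts_per_cell(species_raster, px_per_cell, n_species)
    comm <- community_matrix(counts, cell_centres(landscape))

    structure(list(species_raster = species_raster, community = comm,
                   landscape = landscape, px_per_cell = px_per_cell,
                   params = list(n_species = n_species,
                                 niche_strength = niche_strength,
                                 aggregation = aggregation,
                                 affinity = affinity, optimum = optimum,
                                 seed = seed)),
              class = "synthetic_truth")
  })
}

# Tabulate species (or cluster) counts per px_per_cell block; NA pixels are
# skipped and trailing partial (edge) cells are kept. Rows follow
# column-major cell order, matching cell_centres().
pixel_counts_per_cell <- function(raster, px_per_cell, n_classes) {
  pr <- nrow(raster); pc <- ncol(raster)
  ch <- ceiling(pr / px_per_cell); cw <- ceiling(pc / px_per_cell)
  cell_row <- (rep(seq_len(pr), times = pc) - 1L) %/% px_per_cell
  cell_col <- (rep(seq_len(pc), each = pr) - 1L) %/% px_per_cell
  keep <- !is.na(as.integer(raster))
  cell_id <- cell_row + ch * cell_col + 1L # column-major over cells
  tab <- table(factor(cell_id[keep], levels = seq_len(ch * cw)),
               factor(as.integer(raster)[keep], levels = seq_len(n_classes)))
  m <- matrix(as.integer(tab), ch * cw, n_classes)
  colnames(m) <- paste0("sp", seq_len(n_classes))
  m
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$species_raster), "x",
      ncol(x$species_raster), " pixels, ", x$params$n_species,
      " species (niche_strength=", x$params$niche_strength,
      ", aggregation=", x$params$aggregation, ")\n", sep = "")
  invisible(x)
}
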