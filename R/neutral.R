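#' Fat-tailed dispersal kernel
#'
#' Two-dimensional Student-t-type dispersal kernel with radial density
#' `f(r) proportional to r * (1 + r^2/(tau*sigma^2))^(-(tau+2)/2)` and
#' uniform direction. `sigma` sets the scale (conceptually the mean
#' dispersal distance) and `tau` the fatness of the tail; as `tau` grows
#' the kernel converges to the Rayleigh/Gaussian kernel of scale `sigma`
#' (mean distance `sigma * sqrt(pi/2)`).
#'
#' @param sigma scale in cell units (> 0).
#' @param tau tail-fatness parameter (> 0).
#' @return object of class `dispersal_kernel`.
#' @export
dispersal_kernel <- function(sigma, tau) {
  stopifnot(is.finite(sigma), sigma > 0, is.finite(tau), tau > 0)
  structure(list(sigma = sigma, tau = tau), class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat("<dispersal_kernel> sigma =", x$sigma, ", tau =", x$tau, "\n")
  invisible(x)
}

#' Draw displacements from a dispersal kernel
#'
#' Samples radial distances by inverting the closed-form CDF
#' `F(r) = 1 - (1 + r^2/(tau*sigma^2))^(-tau/2)` and pairs them with
#' uniform angles.
#'
#' @param kernel a [dispersal_kernel()].
#' @param n number of draws.
#' @param seed integer seed.
#' @return data.frame with continuous displacements `dx`, `dy` (cell
#'   units).
#' @export
sample_kernel <- function(kernel, n, seed = NULL) {
  stopifnot(inherits(kernel, "dispersal_kernel"), n >= 1)
  with_seed(seed, {
    u <- stats::runif(n)
    # r = sigma * sqrt(tau * ((1-u)^(-2/tau) - 1)), via expm1 for large tau
    r <- kernel$sigma * sqrt(kernel$tau *
                               expm1((-2 / kernel$tau) * log1p(-u)))
    theta <- stats::runif(n, 0, 2 * pi)
    data.frame(dx = r * cos(theta), dy = r * sin(theta))
  })
}

#' Configure a spatial neutral coalescent simulation
#'
#' @param landscape a [gen_landscape()] arena; its `density` raster gives
#'   individuals per cell and `forest_type` the niches seen by the aware
#'   mode.
#' @param nu per-birth speciation probability in (0, 1].
#' @param kernels a single [dispersal_kernel()] (naive/global modes) or a
#'   list of one kernel per forest type (aware mode).
#' @param m cross-type mixing acceptance probability in `[0, 1]` (aware
#'   mode; `m = 1` removes the penalty and reduces to the naive code
#'   path).
#' @param mode `"naive"` (single arena, one kernel), `"aware"` (per-type
#'   kernels, penalised cross-type dispersal) or `"global"` (spatially
#'   implicit: the parent is uniform over the other J - 1 individuals,
#'   the well-mixed limit with an analytic richness expectation).
#' @param sample data.frame with columns `row`, `col`, `n`: individuals
#'   sampled per cell. Default: one individual in every cell.
#' @param seed integer seed (full determinism contract).
#' @param max_events guard on the total number of coalescent events.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(landscape, nu, kernels, m = 1,
                       mode = c("naive", "aware", "global"),
                       sample = NULL, seed = 1, max_events = 1e9) {
  mode <- match.arg(mode)
  stopifnot(inherits(landscape, "landscape"), nu > 0, nu <= 1,
            m >= 0, m <= 1)
  if (inherits(kernels, "dispersal_kernel")) kernels <- list(kernels)
  stopifnot(all(vapply(kernels, inherits, logical(1), "dispersal_kernel")))
  if (mode == "aware" && length(kernels) != landscape$n_types &&
      length(kernels) != 1)
    stop("aware mode needs one kernel per forest type (or a single shared one)")
  if (mode != "aware" && length(kernels) != 1)
    stop(mode, " mode takes a single kernel")
  if (is.null(sample)) {
    cc <- expand.grid(row = seq_len(landscape$height),
                      col = seq_len(landscape$width))
    sample <- data.frame(row = cc$row, col = cc$col, n = 1L)
  }
  stopifnot(all(c("row", "col", "n") %in% names(sample)))
  if (any(sample$row < 1 | sample$row > landscape$height |
            sample$col < 1 | sample$col > landscape$width))
    stop("sampled cells fall outside the landscape")
  dens <- landscape$density[cbind(sample$row, sample$col)]
  if (any(sample$n > dens))
    stop("sample size exceeds cell density in some cells")
  structure(list(landscape = landscape, nu = nu, kernels = kernels, m = m,
                 mode = mode, sample = sample, seed = seed,
                 max_events = max_events),
            class = "sim_config")
}

#' Run a backwards-in-time neutral coalescent census
#'
#' Traces one lineage per sampled individual backwards in time: at each
#' event a uniformly chosen active lineage either speciates (probability
#' `nu`, founding a species for all its descendants) or moves to a parent
#' drawn through its dispersal kernel (displacements redrawn until they
#' land inside the closed landscape; in aware mode cross-forest-type
#' proposals are accepted with probability `m`, otherwise redrawn) and a
#' uniform parent slot within the target cell's density; two lineages
#' meeting in the same slot coalesce. The process ends when every lineage
#' has speciated (a single surviving lineage is its own most recent common
#' ancestor and founds the final species).
#'
#' @param config a [sim_config()].
#' @return object of class `census`: data.frame with `row`, `col`, `x`,
#'   `y` (sampled cell centres) and `species` (dense integer ids in
#'   speciation order); simulation diagnostics (event and mixing counters)
#'   in `attr(, "diagnostics")`.
#' @export
coalescent_census <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$landscape
  n_types <- L$n_types
  kernels <- config$kernels
  if (config$mode == "aware" && length(kernels) == 1)
    kernels <- rep(kernels, n_types)
  sigma <- vapply(kernels, `[[`, numeric(1), "sigma")
  tau <- vapply(kernels, `[[`, numeric(1), "tau")
  mode_code <- match(config$mode, c("naive", "aware", "global")) - 1L
  smp <- config$sample
  res <- with_seed(config$seed,
    coalesce_cpp(L$forest_type, L$density, sigma, tau, config$nu,
                 config$m, mode_code,
                 as.matrix(smp[, c("row", "col", "n")]),
                 config$max_events, 1e6))
  cs <- L$cell_size
  rows <- rep(smp$row, smp$n); cols <- rep(smp$col, smp$n)
  out <- data.frame(row = rows, col = cols,
                    x = L$origin[1] + (cols - 0.5) * cs,
                    y = L$origin[2] + (rows - 0.5) * cs,
                    species = res$species)
  structure(out, class = c("census", "data.frame"),
            diagnostics = res[c("events", "n_species", "cross_proposals",
                                "cross_accepts")],
            config = config)
}

#' Tabulate a census into a community matrix
#'
#' Counts the individuals of each species in every sampled cell; the total
#' abundance is conserved.
#'
#' @param census a [coalescent_census()] result.
#' @param landscape the arena the census was sampled from (defaults to the
#'   census' own configuration).
#' @return a [community_matrix()] with one row per sampled cell.
#' @export
census_to_community <- function(census, landscape = NULL) {
  landscape <- landscape %||% attr(census, "config")$landscape
  cell <- paste0(census$row, "_", census$col)
  ucell <- unique(cell)
  n_sp <- max(census$species)
  tab <- table(factor(cell, levels = ucell),
               factor(census$species, levels = seq_len(n_sp)))
  counts <- matrix(as.integer(tab), length(ucell), n_sp)
  colnames(counts) <- paste0("sp", seq_len(n_sp))
  first <- match(ucell, cell)
  community_matrix(counts, cbind(census$x[first], census$y[first]),
                   ids = paste0("cell_", ucell))
}

#' @export
print.census <- function(x, ...) {
  d <- attr(x, "diagnostics")
  cat("<census> ", nrow(x), " individuals, ", d$n_species, " species (",
      format(d$events, big.mark = ","), " events)\n", sep = "")
  invisible(x)
}
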