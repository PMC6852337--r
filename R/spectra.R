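#' Default band wavelengths for synthetic scenes
#'
#' 42 bands from 400 to 2450 nm in 50-nm steps, spanning the visible,
#' near-infrared and shortwave-infrared regions and deliberately including
#' the noisy sensor extremes (< 420 nm, > 2400 nm) and the atmospheric water
#' absorption windows (1350-1480 and 1780-2032 nm) so that the band
#' filtering and resampling stages are exercised.
#'
#' @return numeric vector of wavelengths in nanometres.
#' @export
default_wavelengths <- function() seq(400, 2450, by = 50)

# Smooth vegetation-like base reflectance as a function of wavelength (nm):
# dark visible with a small green bump, sharp red edge, NIR plateau, water
# absorption dips and a declining SWIR tail.
vegetation_base <- function(wl) {
  vis <- 0.025 + 0.035 * exp(-(wl - 550)^2 / (2 * 35^2))
  edge <- 1 / (1 + exp(-(wl - 705) / 12))
  plateau <- 0.48 * exp(-pmax(wl - 1300, 0) / 1800)
  dip <- 0.30 * exp(-(wl - 1440)^2 / (2 * 70^2)) +
    0.25 * exp(-(wl - 1920)^2 / (2 * 90^2))
  pmax(vis * (1 - edge) + edge * pmax(plateau - dip, 0.02), 0.01)
}

#' Generate per-species mean reflectance spectra
#'
#' Each species mean is a shared vegetation-like curve plus a smooth,
#' species-specific perturbation, clipped to `[0, 1]`; per-band
#' within-species standard deviations are constant by default.
#'
#' @param n_species number of species.
#' @param wavelengths band centres in nm.
#' @param separation scale of the between-species perturbations
#'   (reflectance units).
#' @param sd within-species standard deviation per band.
#' @param seed integer seed.
#' @return an object of class `species_spectra` with elements `mean`
#'   (species x band matrix), `sd` (same shape) and `wavelengths`.
#' @export
gen_spectra <- function(n_species, wavelengths = default_wavelengths(),
                        separation = 0.05, sd = 0.01, seed = 1) {
  stopifnot(n_species >= 1, length(wavelengths) >= 2, sd >= 0)
  B <- length(wavelengths)
  with_seed(seed, {
    base <- vegetation_base(wavelengths)
    m <- matrix(0, n_species, B)
    tfrac <- (seq_len(B) - 1) / (B - 1)
    phase <- stats::runif(n_species, 0, 2 * pi)
    for (s in seq_len(n_species)) {
      walk <- cumsum(stats::rnorm(B))
      walk <- stats::filter(walk, rep(1 / 5, 5), circular = TRUE)
      walk <- as.numeric(walk) / max(abs(walk), 1e-9)
      # a species-specific smooth signature (distinct frequency + phase)
      # guarantees separable shapes; the perturbation is multiplicative so
      # band ratios (hence NDVI) stay stable
      sig <- sin(2 * pi * (1 + (s - 1) / 2) * tfrac + phase[s])
      m[s, ] <- pmin(pmax(base * (1 + separation * 4 *
                                    (0.75 * sig + 0.25 * walk)), 0), 1)
    }
    structure(list(mean = m, sd = matrix(sd, n_species, B),
                   wavelengths = wavelengths),
              class = "species_spectra")
  })
}

#' Species spectra from explicit mean vectors
#'
#' @param means species x band matrix of mean reflectance in `[0, 1]`.
#' @param wavelengths band centres (nm).
#' @param sd within-species standard deviation (scalar or matrix).
#' @return a `species_spectra` object.
#' @export
species_spectra <- function(means, wavelengths, sd = 0) {
  means <- as.matrix(means)
  stopifnot(ncol(means) == length(wavelengths),
            all(means >= 0 & means <= 1), all(sd >= 0))
  if (length(sd) == 1) sd <- matrix(sd, nrow(means), ncol(means))
  structure(list(mean = means, sd = as.matrix(sd), wavelengths = wavelengths),
            class = "species_spectra")
}

#' Synthesise a hyperspectral reflectance cube from a known community
#'
#' Every pixel's spectrum is its species' mean plus seeded Gaussian noise,
#' clipped to `[0, 1]`. A fraction of pixels is planted as invalid: half of
#' them receive a flat low-NDVI spectrum (bare/shadowed ground), the other
#' half a solar zenith angle above 50 degrees; valid pixels get zenith
#' angles below 50 degrees. A per-pixel zenith channel and the band
#' wavelengths are carried with the cube so the downstream quality filters
#' can be exercised.
#'
#' @param truth a [gen_community()] result.
#' @param spectra a [species_spectra()] object covering every species in
#'   `truth`.
#' @param noise_sd extra per-band Gaussian noise (reflectance units) added on
#'   top of the spectra's own `sd`.
#' @param invalid_fraction fraction of pixels planted invalid, in `[0, 1]`.
#' @param seed integer seed.
#' @return an object of class `reflectance_cube`: `reflectance` (rows x cols
#'   x bands array), `wavelengths`, `zenith` (degrees), `pixel_size` (m) and
#'   the logical `planted_invalid` raster.
#' @export
gen_cube <- function(truth, spectra, noise_sd = 0.0, invalid_fraction = 0,
                     seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(spectra, "species_spectra"),
            invalid_fraction >= 0, invalid_fraction <= 1, noise_sd >= 0)
  sp <- truth$species_raster
  if (max(sp) > nrow(spectra$mean))
    stop("species ", max(sp), " present in truth has no spectrum")
  pr <- nrow(sp); pc <- ncol(sp); npx <- pr * pc
  B <- length(spectra$wavelengths)

  with_seed(seed, {
    refl <- spectra$mean[as.integer(sp), , drop = FALSE]
    tot_sd <- sqrt(spectra$sd[as.integer(sp), , drop = FALSE]^2 + noise_sd^2)
    if (any(tot_sd > 0))
      refl <- refl + matrix(stats::rnorm(npx * B), npx, B) * tot_sd
    zenith <- matrix(stats::runif(npx, 10, 49), pr, pc)
    planted <- matrix(FALSE, pr, pc)
    n_inv <- round(invalid_fraction * npx)
    if (n_inv > 0) {
      idx <- sample.int(npx, n_inv)
      planted[idx] <- TRUE
      half <- idx[seq_len(ceiling(n_inv / 2))]
      rest <- setdiff(idx, half)
      refl[half, ] <- matrix(0.3 + stats::rnorm(length(half) * B, 0, 0.005),
                             length(half), B) # flat spectrum, NDVI ~ 0
      if (length(rest)) zenith[rest] <- stats::runif(length(rest), 50.01, 70)
    }
    refl <- pmin(pmax(refl, 0), 1)
    cube <- array(refl, dim = c(pr, pc, B))
    pixel_size <- truth$landscape$cell_size / truth$px_per_cell
    structure(list(reflectance = cube, wavelengths = spectra$wavelengths,
                   zenith = zenith, pixel_size = pixel_size,
                   planted_invalid = planted),
              class = "reflectance_cube")
  })
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat("<reflectance_cube> ", d[1], "x", d[2], " pixels of ", x$pixel_size,
      " m, ", d[3], " bands (", min(x$wavelengths), "-", max(x$wavelengths),
      " nm)\n", sep = "")
  invisible(x)
}
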