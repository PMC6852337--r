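# Shared fixtures and independent oracles used across the suite.

# Brute-force Bray-Curtis straight from the defining sum, element by element.
bc_oracle <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      num <- 0; den <- 0
      for (i in seq_len(ncol(x))) {
        num <- num + abs(x[j, i] - x[k, i])
        den <- den + x[j, i] + x[k, i]
      }
      d[j, k] <- num / den
    }
  }
  d
}

# Exhaustive Mantel permutation p-value by direct enumeration (independent
# of the package's all_perms helper): two-sided on |r|.
mantel_oracle_p <- function(dx, dy) {
  n <- nrow(dx)
  ut <- upper.tri(dx)
  r_obs <- cor(dx[ut], dy[ut])
  perms <- expand.grid(rep(list(seq_len(n)), n))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ]
  r_all <- apply(perms, 1, function(p) {
    p <- as.integer(p)
    cor(dx[ut], dy[p, p][ut])
  })
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# Small clean scene: 3 well-separated species, mild niche + clustering,
# low-noise cube. Used by the spectral recovery checks.
make_clean_scene <- function(seed = 42, width = 20, height = 20) {
  L <- gen_landscape(width, height, n_types = 3, seed = seed)
  truth <- gen_community(L, n_species = 3, niche_strength = 1,
                         aggregation = 3, px_per_cell = 5,
                         seed = seed + 1)
  spectra <- gen_spectra(3, separation = 0.08, sd = 0.005, seed = seed + 2)
  cube <- gen_cube(truth, spectra, noise_sd = 0.005,
                   invalid_fraction = 0.02, seed = seed + 3)
  list(landscape = L, truth = truth, spectra = spectra, cube = cube)
}

# Site-pair table generated exactly from a known GDM (no noise), together
# with the generating parameters.
make_exact_gdm_pairs <- function(n_sites = 60, seed = 42) {
  set.seed(seed)
  coords <- cbind(runif(n_sites, 0, 1000), runif(n_sites, 0, 1000))
  env <- data.frame(elev = runif(n_sites, 0, 100))
  pairs <- build_site_pairs(matrix(0, n_sites, n_sites), env,
                            coords = coords)
  kd <- unname(quantile(pairs$distance, c(0, 0.5, 1)))
  ke <- c(0, 50, 100)
  bd <- c(0.3, 0.5, 0.4); be <- c(0.6, 0.2, 0.7); a0 <- 0.05
  eta <- a0 + ispline_basis(pairs$distance, kd) %*% bd +
    abs(ispline_basis(pairs$x2_elev, ke) -
          ispline_basis(pairs$x1_elev, ke)) %*% be
  pairs$d <- as.numeric(1 - exp(-eta))
  list(pairs = pairs, knots = list(distance = kd, elev = ke),
       beta_distance = bd, beta_elev = be, intercept = a0)
}
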