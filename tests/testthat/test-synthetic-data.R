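test_that("landscape generation is deterministic and respects n_types", {
  L1 <- gen_landscape(20, 15, n_types = 3, seed = 11)
  L2 <- gen_landscape(20, 15, n_types = 3, seed = 11)
  expect_identical(L1, L2)

  L3 <- gen_landscape(10, 10, n_types = 1, seed = 5)
  expect_true(all(L3$forest_type == 1L))

  expect_true(all(dim(L1$forest_type) == c(15, 20)))
  expect_true(all(dim(L1$covariates$elevation) == c(15, 20)))
  expect_true(all(L1$forest_type %in% 1:3))
  expect_true(all(table(L1$forest_type) > 0))
  expect_true(all(L1$density >= 1))

  expect_error(gen_landscape(1, 10), "dimensions")
  expect_error(gen_landscape(3, 3, n_types = 10), "exceeds")
})

test_that("covariate fields carry the requested autocorrelation range", {
  # exponential correlation exp(-3d/range): the semivariogram reaches 95%
  # of its sill at d = range. Estimate the range by least squares on the
  # empirical row-lag correlations.
  f <- gaussian_random_field(100, 100, 20, seed = 21)
  lags <- 1:35
  emp <- vapply(lags, function(l)
    cor(as.vector(f[, 1:(100 - l)]), as.vector(f[, (l + 1):100])),
    numeric(1))
  fit <- optimize(function(r) sum((emp - exp(-3 * lags / r))^2), c(2, 80))
  expect_gt(fit$minimum, 20 * 0.7)
  expect_lt(fit$minimum, 20 * 1.4)

  # near-unit marginal variance
  expect_gt(var(as.vector(f)), 0.7)
  expect_lt(var(as.vector(f)), 1.3)
})

test_that("community generation conserves pixels and is deterministic", {
  L <- gen_landscape(8, 8, n_types = 2, seed = 3)
  t1 <- gen_community(L, n_species = 6, niche_strength = 1, aggregation = 2,
                      px_per_cell = 4, seed = 9)
  t2 <- gen_community(L, n_species = 6, niche_strength = 1, aggregation = 2,
                      px_per_cell = 4, seed = 9)
  expect_identical(t1$species_raster, t2$species_raster)

  # per-cell abundances are exactly the pixel counts
  expect_true(all(rowSums(t1$community$counts) == 16))
  expect_equal(sum(t1$community$counts), length(t1$species_raster))
  one <- t1$species_raster[1:4, 1:4] # cell 1 block
  expect_equal(unname(t1$community$counts[1, ]),
               unname(tabulate(one, nbins = 6)))
})

test_that("strong type-exclusive niches drive cross-type dissimilarity to 1", {
  L <- gen_landscape(10, 10, n_types = 2, type_pattern = "bands", seed = 4)
  tr <- gen_community(L, n_species = 8, niche_strength = 50,
                      aggregation = 0, px_per_cell = 4, seed = 5)
  d <- bray_curtis(tr$community)
  ft <- as.vector(L$forest_type)
  cross <- outer(ft, ft, `!=`)
  expect_gt(min(d[cross]), 0.99)
})

test_that("neutral assignment shows no distance decay (null calibration)", {
  # niche_strength = 0, aggregation = 0: composition is i.i.d. uniform, so
  # the correlogram should find nothing and a GDM should explain ~nothing
  hits <- 0; classes <- 0; explained <- numeric(8)
  for (s in 1:8) {
    L <- gen_landscape(9, 9, n_types = 1, seed = 100 + s)
    tr <- gen_community(L, n_species = 12, niche_strength = 0,
                        aggregation = 0, px_per_cell = 4, seed = 200 + s)
    d <- bray_curtis(tr$community)
    cg <- mantel_correlogram(d, n_boot = 100, seed = 300 + s)
    ok <- !is.na(cg$mr)
    hits <- hits + sum(cg$ci_lo[ok] <= 0 & cg$ci_hi[ok] >= 0)
    classes <- classes + sum(ok)
    pairs <- build_site_pairs(d, cell_environment(L))
    fit <- suppressWarnings(fit_gdm(pairs, c("distance", "elevation")))
    explained[s] <- fit$explained
  }
  expect_gt(hits / classes, 0.9)
  expect_lt(mean(explained), 2)
})

test_that("cube synthesis reproduces spectra exactly at zero noise", {
  L <- gen_landscape(4, 4, n_types = 1, seed = 1)
  tr <- gen_community(L, n_species = 3, px_per_cell = 3, seed = 2)
  sp <- gen_spectra(3, sd = 0, seed = 3)
  cube <- gen_cube(tr, sp, noise_sd = 0, invalid_fraction = 0, seed = 4)
  px <- matrix(cube$reflectance, 144, length(sp$wavelengths))
  expect_equal(px, sp$mean[as.vector(tr$species_raster), ],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(gen_cube(tr, sp, seed = 4)$reflectance,
                   cube$reflectance)

  # a species without a spectrum is an error
  expect_error(gen_cube(tr, species_spectra(sp$mean[1:2, ],
                                            sp$wavelengths)),
               "no spectrum")
})

test_that("planted invalid pixels match the requested fraction", {
  L <- gen_landscape(10, 10, n_types = 1, seed = 1)
  tr <- gen_community(L, n_species = 3, px_per_cell = 5, seed = 2)
  sp <- gen_spectra(3, sd = 0.002, seed = 3)
  cube <- gen_cube(tr, sp, noise_sd = 0.002, invalid_fraction = 0.3,
                   seed = 4)
  frac <- mean(cube$planted_invalid)
  expect_lt(abs(frac - 0.3), 0.02)
  # planted pixels actually fail the quality filters
  mask <- filter_pixels(cube)
  expect_true(all(!mask$mask[cube$planted_invalid]))
})
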