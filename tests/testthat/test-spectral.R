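# A tiny hand-built cube: 2x2 pixels, 4 bands at 650/800/1600/2100 nm.
tiny_cube <- function(spectra, zenith = matrix(20, 2, 2)) {
  refl <- array(0, dim = c(2, 2, 4))
  for (p in 1:4) refl[(p - 1) %% 2 + 1, (p - 1) %/% 2 + 1, ] <- spectra[p, ]
  list(reflectance = refl, wavelengths = c(650, 800, 1600, 2100),
       zenith = zenith, pixel_size = 10)
}

test_that("NDVI and zenith filters reject the documented cases", {
  sp <- rbind(c(0.1, 0.5, 0.1, 0.1),   # NDVI = 0.4/0.6 ~ 0.667 -> rejected
              c(0.3, 0.3, 0.1, 0.1),   # NIR = red -> NDVI 0 -> rejected
              c(0.02, 0.90, 0.1, 0.1), # NDVI ~ 0.9565 -> retained
              c(0.02, 0.90, 0.1, 0.1)) # retained but zenith 60 below
  zen <- matrix(c(20, 20, 20, 60), 2, 2)
  m <- filter_pixels(tiny_cube(sp, zen))
  expect_identical(as.vector(m$mask), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(unname(m$counts["n_ndvi_fail"]), 2)
  expect_equal(unname(m$counts["n_zenith_fail"]), 1)
  expect_equal(unname(m$counts["n_pass"]), 1)

  # raising the NDVI threshold can only remove pixels
  m_low <- filter_pixels(tiny_cube(sp, zen), ndvi_threshold = 0.5)
  expect_true(all(m$mask <= m_low$mask))

  # missing red/NIR coverage is an error
  bad <- tiny_cube(sp); bad$wavelengths <- c(1000, 1200, 1600, 2100)
  expect_error(filter_pixels(bad), "bracket")
})

test_that("brightness normalisation is the L2 projection onto the sphere", {
  expect_equal(brightness_normalise(c(3, 4)), c(0.6, 0.8))
  v <- c(0.2, 0.5, 0.1)
  expect_equal(brightness_normalise(7.3 * v), brightness_normalise(v))
  u <- v / sqrt(sum(v^2))
  expect_equal(brightness_normalise(u), u)
  expect_error(brightness_normalise(c(0, 0, 0)), "all-zero")
  m <- rbind(c(3, 4), c(1, 0))
  expect_equal(brightness_normalise(m), rbind(c(0.6, 0.8), c(1, 0)))
  expect_error(brightness_normalise(rbind(c(1, 2), c(0, 0))), "row")
})

test_that("band resampling drops noisy/water bands and averages groups", {
  wl <- c(400, 410, 450, 500, 550, 1400, 1600, 1650, 2450)
  refl <- array(rep(1:9, each = 4), dim = c(2, 2, 9))
  cube <- list(reflectance = refl, wavelengths = wl,
               zenith = matrix(0, 2, 2), pixel_size = 1)
  out <- resample_bands(cube)
  # 400/410 (< 420), 1400 (water), 2450 (> 2400) removed; VNIR group
  # (450,500,550) -> mean band value 4; SWIR group (1600,1650) -> 7.5
  expect_equal(out$wavelengths, c(500, 1625))
  expect_equal(as.vector(out$reflectance[1, 1, ]), c(4, 7.5))

  # VNIR averaging of (0.1, 0.2, 0.3) gives 0.2
  cube2 <- list(reflectance = array(rep(c(0.1, 0.2, 0.3), each = 1),
                                    dim = c(1, 1, 3)),
                wavelengths = c(450, 500, 550),
                zenith = matrix(0, 1, 1), pixel_size = 1)
  expect_equal(as.vector(resample_bands(cube2)$reflectance), 0.2)

  expect_error(resample_bands(list(reflectance = array(1, c(1, 1, 2)),
                                   wavelengths = c(400, 2450),
                                   zenith = matrix(0, 1, 1))),
               "no bands")
})

test_that("k-means clustering is seeded, exact on separable data", {
  set.seed(1)
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 10), 30))
  m1 <- fit_clusters(x, 2, seed = 5)
  m2 <- fit_clusters(x, 2, seed = 5)
  expect_identical(m1, m2)
  a <- assign_clusters(m1, x)
  expect_equal(length(unique(a[1:30])), 1)
  expect_equal(length(unique(a[31:60])), 1)
  expect_false(a[1] == a[31])

  # two orthogonal noiseless spectra, k = 2: perfect partition, WSS = 0
  y <- rbind(matrix(rep(c(1, 0), 5), 5, 2, byrow = TRUE),
             matrix(rep(c(0, 1), 5), 5, 2, byrow = TRUE))
  m3 <- fit_clusters(y, 2, seed = 1)
  expect_equal(m3$wss, 0)

  # k = 1: WSS equals the total sum of squares about the mean
  m4 <- fit_clusters(x, 1, seed = 1)
  expect_equal(m4$wss, sum(scale(x, scale = FALSE)^2))

  # duplicated rows get identical assignments
  z <- x[c(1:10, 1:10), ]
  az <- assign_clusters(m1, z)
  expect_identical(az[1:10], az[11:20])

  expect_error(fit_clusters(x[1:3, ], 5), "exceeds")

  # mini-batch variant is deterministic too and broadly recovers structure
  mb1 <- fit_clusters(x, 2, seed = 5, method = "minibatch", iter = 20)
  mb2 <- fit_clusters(x, 2, seed = 5, method = "minibatch", iter = 20)
  expect_identical(mb1, mb2)
  ab <- assign_clusters(mb1, x)
  expect_equal(length(unique(ab[1:30])), 1)
  expect_false(ab[1] == ab[31])
})

test_that("the WSS elbow flags a planted cluster count", {
  set.seed(7)
  centers <- cbind(c(0, 50, 0, 50, 100), c(0, 0, 50, 50, 100))
  x <- centers[rep(1:5, each = 40), ] + matrix(rnorm(400, sd = 0.5), 200, 2)
  diag <- select_k(x, k_grid = 2:8, seed = 3, nstart = 5)
  expect_equal(attr(diag, "knee"), 5)
  expect_equal(diag$mean_wss, diag$wss / 200)

  # WSS trends downward in k
  expect_lt(diag$wss[7], diag$wss[1])

  # degenerate grid: diagnostics only, no knee
  d1 <- select_k(x, k_grid = 3, seed = 3)
  expect_equal(nrow(d1), 1)
  expect_true(is.na(attr(d1, "knee")))
  expect_error(select_k(x, k_grid = c(5, 3)), "ascending")
})

test_that("gridding counts clusters per cell and enforces the coverage rule", {
  # 10x10 pixel raster of 5 m pixels -> 10 m cells hold 4 pixels each
  r <- matrix(1L, 10, 10)
  r[, 6:10] <- 2L
  r[1, 1] <- NA; r[2, 1] <- NA; r[1, 2] <- NA # cell 1 at 25% coverage
  r[3, 1] <- NA; r[4, 1] <- NA; r[3, 2] <- NA; r[4, 2] <- NA # cell 2: 0%
  cm <- grid_abundances(r, pixel_size = 5, cell_size = 10,
                        min_coverage = 0.25)
  expect_equal(length(attr(cm, "dropped")), 1) # only the 0% cell dropped
  expect_equal(cm$coverage[1], 0.25) # 25% retained ("at least 25%")
  # a 24%-coverage cell would be excluded
  cm2 <- grid_abundances(r, pixel_size = 5, cell_size = 10,
                         min_coverage = 0.26)
  expect_equal(length(attr(cm2, "dropped")), 2)
  # counting: full single-cluster cell
  expect_equal(unname(cm$counts[2, ]), c(4, 0))
  # conservation: column sums equal valid pixels
  expect_equal(sum(cm$counts), sum(!is.na(r)))
  expect_error(grid_abundances(r, pixel_size = 5, cell_size = 2), "at least")
})

test_that("the spectral pipeline recovers a clean synthetic scene", {
  scn <- make_clean_scene(seed = 42)
  res <- spectral_species(scn$cube, k = 3, seed = 6)
  ok <- !is.na(res$cluster_raster) & !scn$cube$planted_invalid
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(res$cluster_raster[ok],
                                   scn$truth$species_raster[ok])
  expect_gt(ari, 0.95)

  keep <- as.integer(sub("cell_", "", res$community$ids))
  tb <- bray_curtis(scn$truth$community)
  mt <- mantel_test(tb[keep, keep], bray_curtis(res$community),
                    n_perm = 99, seed = 1)
  expect_gt(mt$statistic, 0.9)
  expect_lt(mt$p.value, 0.05)
})

test_that("bray_curtis agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(3)
  x <- matrix(rpois(60, 4) + 1, 6, 10)
  expect_equal(unname(bray_curtis(x)),
               unname(as.matrix(vegan::vegdist(x, method = "bray"))),
               tolerance = 1e-12)
})
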