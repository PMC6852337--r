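test_that("site-pair tables carry pairs, distances and orthogonal contrasts", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3)
  coords <- cbind(c(0, 3, 0), c(0, 0, 4))
  env <- data.frame(elev = c(1, 2, 3),
                    forest_type = factor(c("a", "b", "c")))
  pairs <- build_site_pairs(d, env, coords)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$distance, c(3, 4, 5))
  expect_equal(pairs$d, c(.2, .3, .4))
  # round-trip of metric coordinates
  expect_equal(attr(pairs, "coords"), coords)

  # Helmert contrasts for a balanced 3-type design: zero-sum, orthogonal
  site_env <- attr(pairs, "env")
  expect_equal(sum(site_env$ft_c1), 0)
  expect_equal(sum(site_env$ft_c2), 0)
  expect_equal(sum(site_env$ft_c1 * site_env$ft_c2), 0)

  expect_error(build_site_pairs(d, env[1:2, ], coords), "match")
})

test_that("I-splines are monotone, normalised and integrate their M-splines", {
  kn <- c(0, 0.4, 1)
  x <- seq(0, 1, length.out = 101)
  I <- ispline_basis(x, kn)
  expect_equal(ncol(I), 3)
  expect_true(all(I[1, ] == 0))           # zero at the lower knot
  expect_true(all(I[101, ] == 1))         # one at the upper knot
  expect_true(all(diff(I) >= -1e-12))     # monotone non-decreasing
  expect_true(all(I >= 0 & I <= 1))
  # values outside the knot range are clamped
  expect_equal(ispline_basis(c(-5, 7), kn), rbind(rep(0, 3), rep(1, 3)))

  # quadrature oracle: I equals the running integral of M
  for (xx in c(0.15, 0.4, 0.77)) {
    for (j in 1:3) {
      quad <- integrate(function(t) mspline_basis(t, kn)[, j], 0, xx,
                        rel.tol = 1e-10)$value
      expect_equal(ispline_basis(xx, kn)[1, j], quad, tolerance = 1e-8)
    }
  }
  expect_error(ispline_basis(0.5, c(1, 1)), "strictly increasing")
})

test_that("a noiseless GDM is recovered to machine precision", {
  gt <- make_exact_gdm_pairs(n_sites = 60, seed = 42)
  fit <- fit_gdm(gt$pairs, c("distance", "elev"), knots = gt$knots)
  expect_true(fit$converged)
  expect_gt(fit$explained, 99)
  err <- max(abs(c(fit$coefficients$distance - gt$beta_distance,
                   fit$coefficients$elev - gt$beta_elev)))
  expect_lt(err / max(abs(c(gt$beta_distance, gt$beta_elev))), 0.05)
  expect_equal(fit$intercept, gt$intercept, tolerance = 1e-6)

  # fitted values in [0, 1); distance spline max = sum of its coefficients
  mu <- predict(fit, gt$pairs)
  expect_true(all(mu >= 0 & mu < 1))
  spl <- gdm_spline(fit, "distance")
  expect_equal(max(spl$y), sum(fit$coefficients$distance))
  expect_true(all(diff(spl$y) >= -1e-12))

  # invariance to pair-row order and to swapping sites within a pair
  set.seed(1)
  p2 <- gt$pairs[sample.int(nrow(gt$pairs)), ]
  f2 <- fit_gdm(p2, c("distance", "elev"), knots = gt$knots)
  expect_equal(f2$coefficients, fit$coefficients, tolerance = 1e-6)
  p3 <- gt$pairs
  p3[, c("x1_elev", "x2_elev")] <- p3[, c("x2_elev", "x1_elev")]
  f3 <- fit_gdm(p3, c("distance", "elev"), knots = gt$knots)
  expect_equal(f3$coefficients, fit$coefficients, tolerance = 1e-6)
})

test_that("degenerate predictors and zeroed models behave as documented", {
  gt <- make_exact_gdm_pairs(n_sites = 30, seed = 7)
  p <- gt$pairs
  p$x1_flat <- 1; p$x2_flat <- 1
  attr(p, "vars") <- c(attr(p, "vars"), "flat")
  expect_warning(fit_gdm(p, c("distance", "flat")), "degenerate")

  # all coefficients zero: d-hat = 1 - exp(-a0); a0 = 0 gives 0
  fit <- fit_gdm(gt$pairs, "distance")
  z <- fit
  z$coefficients$distance[] <- 0
  z$intercept <- 0.5
  expect_equal(unique(round(predict(z, gt$pairs), 12)),
               1 - exp(-0.5))
  z$intercept <- 0
  expect_true(all(predict(z, gt$pairs) == 0))

  expect_error(fit_gdm(gt$pairs[1:5, ], "distance"), "at least 10")
})

test_that("shuffled responses explain (almost) nothing", {
  gt <- make_exact_gdm_pairs(n_sites = 40, seed = 3)
  set.seed(10)
  ex <- vapply(1:10, function(i) {
    p <- gt$pairs
    p$d <- sample(p$d)
    suppressWarnings(fit_gdm(p, c("distance", "elev")))$explained
  }, numeric(1))
  expect_lt(median(ex), 2)
})

test_that("deviance partition satisfies its accounting identity", {
  scn <- make_clean_scene(seed = 7, width = 12, height = 12)
  d <- bray_curtis(scn$truth$community)
  env <- cell_environment(scn$landscape)
  pairs <- build_site_pairs(d, env[, c("x", "y", "elevation", "tch")])
  part <- gdm_partition(pairs)
  expect_equal(part$D + part$E + part$DxE, part$full, tolerance = 1e-8)
  expect_true(all(c(part$D, part$E, part$DxE) >= 0))
  expect_equal(part$unexplained, 100 - part$full)
  # exported splines evaluate on a 100-point grid
  expect_equal(nrow(part$spline_d_only), 100)
  expect_equal(nrow(part$spline_d_plus_dxe), 100)
})

test_that("independent environment yields DxE ~ 0; coordinate-driven env kills unique D", {
  set.seed(5)
  reps <- vapply(1:5, function(s) {
    n <- 45
    coords <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
    env <- data.frame(noise = rnorm(n)) # spatially independent
    pairs <- build_site_pairs(matrix(0, n, n), env, coords)
    kd <- unname(quantile(pairs$distance, c(0, .5, 1)))
    eta <- 0.1 + ispline_basis(pairs$distance, kd) %*% c(.3, .3, .3) +
      abs(ispline_basis(pairs$x2_noise, gdm_knots(env$noise)) -
            ispline_basis(pairs$x1_noise, gdm_knots(env$noise))) %*%
        c(.2, .2, .2)
    pairs$d <- as.numeric(1 - exp(-eta))
    gdm_partition(pairs, "noise")$DxE
  }, numeric(1))
  expect_lt(mean(abs(reps)), 2)

  # environment that is a pure function of the coordinates (1-D transect,
  # response linear in distance so the environment model can mimic it):
  # unique D ~ 0 and the overlap absorbs the distance signal
  n <- 45
  set.seed(6)
  coords <- cbind(sort(runif(n, 0, 1000)), rep(0, n))
  env <- data.frame(xpos = coords[, 1])
  pairs <- build_site_pairs(matrix(0, n, n), env, coords)
  eta <- 0.1 + 0.0012 * pairs$distance
  pairs$d <- as.numeric(1 - exp(-eta))
  part <- gdm_partition(pairs, "xpos")
  expect_lt(part$D, 2.5)
  expect_gt(part$DxE, part$full * 0.5)
})

test_that("permutation importance tracks the generating predictor", {
  gt <- make_exact_gdm_pairs(n_sites = 35, seed = 12)
  fit <- fit_gdm(gt$pairs, c("distance", "elev"), knots = gt$knots)
  imp <- gdm_importance(fit, gt$pairs, n_perm = 8, seed = 3)
  # elev carries real signal: its loss is large and positive
  expect_gt(imp[["elev"]], 5)

  # a pure-noise predictor has ~zero importance and adds ~nothing
  set.seed(13)
  p <- gt$pairs
  env <- attr(p, "env")
  env$junk <- rnorm(nrow(env))
  p$x1_junk <- env$junk[p$site1]; p$x2_junk <- env$junk[p$site2]
  attr(p, "env") <- env
  attr(p, "vars") <- c(attr(p, "vars"), "junk")
  f2 <- fit_gdm(p, c("distance", "elev", "junk"), )
  expect_lt(abs(f2$explained - fit$explained), 1)
  imp2 <- gdm_importance(f2, p, n_perm = 8, seed = 4)
  expect_lt(abs(imp2[["junk"]]), 1)
  expect_gt(imp2[["junk"]], -1) # non-negative up to refit noise
})
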