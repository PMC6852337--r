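test_that("kernel draws follow the closed-form radial law", {
  # Gaussian limit: tau -> Inf gives a Rayleigh kernel with mean
  # sigma * sqrt(pi/2)
  k <- dispersal_kernel(2, 1e6)
  d <- sample_kernel(k, 2e5, seed = 1)
  r <- sqrt(d$dx^2 + d$dy^2)
  expect_lt(abs(mean(r) / (2 * sqrt(pi / 2)) - 1), 0.02)

  # scale family: draws with (2 sigma, tau) are distributed as 2 x draws
  # with (sigma, tau)
  r1 <- with(sample_kernel(dispersal_kernel(1.5, 3), 4000, seed = 2),
             sqrt(dx^2 + dy^2))
  r2 <- with(sample_kernel(dispersal_kernel(3, 3), 4000, seed = 3),
             sqrt(dx^2 + dy^2))
  ks <- suppressWarnings(ks.test(2 * r1, r2))
  expect_gt(ks$p.value, 0.01)

  # isotropy: circular mean resultant length near zero
  d3 <- sample_kernel(dispersal_kernel(2, 4), 2e5, seed = 4)
  r3 <- sqrt(d3$dx^2 + d3$dy^2)
  expect_lt(sqrt(mean(d3$dx / r3)^2 + mean(d3$dy / r3)^2), 0.01)

  expect_error(dispersal_kernel(-1, 2))
  expect_error(dispersal_kernel(2, 0))
})

test_that("censuses are deterministic and respect the speciation limits", {
  L <- gen_landscape(12, 12, n_types = 1, seed = 1)
  cfg <- sim_config(L, nu = 0.02, dispersal_kernel(3, 5), seed = 7)
  c1 <- coalescent_census(cfg)
  c2 <- coalescent_census(cfg)
  expect_identical(c1$species, c2$species)

  # nu = 1: every sampled individual founds its own species
  ca <- coalescent_census(sim_config(L, nu = 1, dispersal_kernel(3, 5),
                                     seed = 3))
  expect_equal(attr(ca, "diagnostics")$n_species, nrow(ca))
  expect_equal(sort(unique(ca$species)), seq_len(nrow(ca)))

  # nu -> 0 on a connected landscape: a single species
  Ls <- gen_landscape(10, 10, n_types = 1, seed = 2)
  rich <- vapply(1:20, function(i)
    attr(coalescent_census(sim_config(Ls, nu = 1e-9,
                                      dispersal_kernel(3, 5),
                                      seed = i)),
         "diagnostics")$n_species, numeric(1))
  expect_gte(mean(rich == 1), 0.95)
})

test_that("well-mixed richness matches the Ewens sampling formula", {
  L <- gen_landscape(20, 20, n_types = 1, seed = 1)
  S <- vapply(1:60, function(i)
    attr(coalescent_census(sim_config(L, nu = 0.05,
                                      dispersal_kernel(1, 1),
                                      mode = "global", seed = i)),
         "diagnostics")$n_species, numeric(1))
  J <- 400
  theta <- 0.05 * (J - 1) / (1 - 0.05)
  ES <- sum(theta / (theta + 0:(J - 1)))
  expect_lt(abs(mean(S) - ES), 3 * sd(S) / sqrt(length(S)))
})

test_that("expected richness is non-decreasing in the speciation rate", {
  L <- gen_landscape(12, 12, n_types = 1, seed = 3)
  mean_S <- vapply(c(1e-4, 1e-3, 1e-2), function(nu)
    mean(vapply(1:40, function(i)
      attr(coalescent_census(sim_config(L, nu = nu,
                                        dispersal_kernel(3, 5),
                                        seed = 500 + i)),
           "diagnostics")$n_species, numeric(1))), numeric(1))
  expect_true(all(diff(mean_S) > 0))
})

test_that("naive censuses show distance decay of similarity", {
  L <- gen_landscape(20, 20, n_types = 1, seed = 4)
  rho <- vapply(1:8, function(i) {
    cfg <- sim_config(L, nu = 0.01, dispersal_kernel(2, 5), seed = 40 + i)
    comm <- census_to_community(coalescent_census(cfg))
    d <- bray_curtis(comm)
    geo <- as.matrix(dist(comm$coords))
    ut <- upper.tri(d)
    classes <- cut(geo[ut], 8)
    cor(as.integer(classes), d[ut], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rho > 0), 0.9)
})

test_that("census tabulation conserves individuals", {
  L <- gen_landscape(6, 6, n_types = 1, seed = 5)
  smp <- data.frame(row = c(1, 1, 2, 4), col = c(1, 2, 3, 4),
                    n = c(3, 2, 4, 1))
  L$density[] <- 5L
  cfg <- sim_config(L, nu = 0.3, dispersal_kernel(2, 5), sample = smp,
                    seed = 9)
  cen <- coalescent_census(cfg)
  comm <- census_to_community(cen)
  expect_equal(sum(comm$counts), 10)
  expect_equal(nrow(comm$counts), 4)
  # manual tally of the first sampled cell
  expect_equal(unname(comm$counts[1, ]),
               unname(tabulate(cen$species[cen$row == 1 & cen$col == 1],
                               nbins = max(cen$species))))

  # single-cell sample map gives a single community row
  one <- census_to_community(coalescent_census(
    sim_config(L, nu = 0.5, dispersal_kernel(2, 5),
               sample = data.frame(row = 2, col = 2, n = 5), seed = 2)))
  expect_equal(nrow(one$counts), 1)
  expect_equal(sum(one$counts), 5)
})

test_that("mixing penalty limits reproduce naive and fully confined dynamics", {
  L <- gen_landscape(24, 24, n_types = 3, type_pattern = "bands", seed = 1)
  kern <- dispersal_kernel(4, 5)
  # m = 1: identical trajectories to the naive mode on a shared seed
  cn <- coalescent_census(sim_config(L, nu = 0.01, kern, mode = "naive",
                                     seed = 5))
  ca <- coalescent_census(sim_config(L, nu = 0.01, list(kern, kern, kern),
                                     m = 1, mode = "aware", seed = 5))
  expect_identical(cn$species, ca$species)

  # m = 0: no lineage crosses a type boundary, so species are confined to
  # one type and cross-type Bray-Curtis is exactly 1
  c0 <- coalescent_census(sim_config(L, nu = 0.01, list(kern, kern, kern),
                                     m = 0, mode = "aware", seed = 6))
  expect_equal(attr(c0, "diagnostics")$cross_accepts, 0)
  comm <- census_to_community(c0)
  d <- bray_curtis(comm)
  ft <- L$forest_type[cbind(c0$row, c0$col)]
  expect_true(all(d[outer(ft, ft, `!=`)] == 1))

  # m = 0.5: cross-type proposals are accepted at rate 0.50 +- 0.01
  prop <- 0; acc <- 0; i <- 0
  while (prop < 1e5) {
    i <- i + 1
    ci <- coalescent_census(sim_config(L, nu = 1e-4,
                                       list(kern, kern, kern),
                                       m = 0.5, mode = "aware",
                                       seed = 100 + i))
    dg <- attr(ci, "diagnostics")
    prop <- prop + dg$cross_proposals
    acc <- acc + dg$cross_accepts
  }
  expect_lt(abs(acc / prop - 0.5), 0.01)
})
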