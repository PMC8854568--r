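# Truth-grid construction and the TLS survey generator.

test_that("uniform config with unit multipliers gives constant stratum slabs", {
  cfg <- scene_config(extent = c(10, 5, 20), strata_boundary = 10,
                      understory_pad_mean = 0.4, canopy_pad_mean = 0.2,
                      edge_gradient = c(1, 0, 0.1),
                      seasonal_multipliers = tibble::tibble(
                        survey = 1L, date = 1L, stratum = "understory",
                        edge_class = "edge", multiplier = 1),
                      heterogeneity_cv = 0)
  g <- build_truth_grid(cfg, 1)
  expect_true(all(g$values[, , 1:10] == 0.4))
  expect_true(all(g$values[, , 11:20] == 0.2))
})

test_that("edge multiplier reproduces the asymptotic PAI curve", {
  eg <- c(beta0 = 5, beta1 = -1.5, beta2 = 0.08)
  # derived from beta0 + beta1 * exp(-beta2 x): x = 0 -> 3.5; x = 500 -> 5
  expect_equal(5 * edge_multiplier(0, eg), 3.5)
  expect_equal(5 * edge_multiplier(500, eg), 5, tolerance = 1e-9)
  # column PAI at the edge is lower by beta1 once the asymptote is reached
  cfg <- scene_config(extent = c(500, 2, 20), strata_boundary = 10,
                      understory_pad_mean = 0.3, canopy_pad_mean = 0.2,
                      edge_gradient = eg, heterogeneity_cv = 0,
                      seasonal_multipliers = tibble::tibble(
                        survey = 1L, date = 1L, stratum = "understory",
                        edge_class = "interior", multiplier = 1))
  g <- build_truth_grid(cfg, 1)
  pai <- column_pai(pad_grid(g$values, g$origin, g$voxel_size,
                             "above_ground"), strata_boundary = 10)
  tot <- pai[pai$stratum == "total", ]
  near <- tot$pai[tot$column_x == 0.5]
  far <- tot$pai[tot$column_x == 499.5]
  # baseline column PAI is 5 = beta0, so the deficit approaches |beta1|
  expect_equal(far[1] - near[1], 1.5 * (exp(-0.08 * 0.5) - exp(-0.08 * 499.5)),
               tolerance = 1e-9)
})

test_that("seasonal multipliers scale stratum PAD multiplicatively", {
  sm <- tibble::tibble(survey = c(1L, 2L, 2L),
                       date = c(1, 2, 2),
                       stratum = c("understory", "understory", "upper_canopy"),
                       edge_class = "interior",
                       multiplier = c(1, 0.947, 1))
  cfg <- scene_config(extent = c(10, 5, 30), strata_boundary = 15,
                      edge_gradient = c(1, 0, 0.1), heterogeneity_cv = 0,
                      seasonal_multipliers = sm, edge_threshold = 0)
  g1 <- build_truth_grid(cfg, 1)
  g2 <- build_truth_grid(cfg, 2)
  expect_equal(g2$values[, , 1:15], g1$values[, , 1:15] * 0.947)
  expect_equal(g2$values[, , 16:30], g1$values[, , 16:30])
})

test_that("truth grids are deterministic given the config seed", {
  cfg <- scene_config(extent = c(10, 5, 20), seed = 99)
  expect_identical(build_truth_grid(cfg, 1)$values,
                   build_truth_grid(cfg, 1)$values)
  cfg2 <- scene_config(extent = c(10, 5, 20), seed = 100)
  expect_false(identical(build_truth_grid(cfg, 1)$values,
                         build_truth_grid(cfg2, 1)$values))
})

test_that("scene_config validates its invariants", {
  expect_error(scene_config(voxel_size = 0), "voxel_size")
  expect_error(scene_config(understory_pad_mean = -1), "means")
  expect_error(scene_config(strata_boundary = 50, extent = c(10, 10, 35)),
               "strata_boundary")
})

test_that("empty grid over flat ground yields one ground return per downward pulse", {
  g <- pad_grid(array(0, c(5, 5, 5)), voxel_size = 1)
  n <- 50
  lay <- with_seed(3, list(
    origins = cbind(runif(n, 0, 5), runif(n, 0, 5), runif(n, 2, 4)),
    dirs = {
      z <- runif(n, -1, -0.2); phi <- runif(n, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      cbind(r * cos(phi), r * sin(phi), z)
    }, max_range = 350))
  p <- simulate_survey(g, lay, seed = 1, ground = c(0.5, 0, 0))
  expect_equal(nrow(p), n)
  expect_true(all(p$is_ground))
  expect_true(all(p$beam_fraction == 1))
  # analytic ray-plane distance: (oz - 0.5) / |dz|
  expect_equal(p$range_m, (p$oz - 0.5) / abs(p$dz), tolerance = 1e-9)
})

test_that("no-hit fraction matches the closed-form survival probability", {
  # horizontal pulses of fixed in-grid length L through homogeneous lambda
  for (tau in c(0.5, 1, 5)) {
    L <- 20
    lam <- tau / L
    g <- pad_grid(array(lam / 0.5, c(20, 20, 4)), voxel_size = 1)
    n <- 1e4
    lay <- with_seed(17, list(
      origins = cbind(rep(1e-9, n), runif(n, 0, 20), runif(n, 0, 4)),
      dirs = cbind(rep(1, n), rep(0, n), rep(0, n)), max_range = 350))
    p <- simulate_survey(g, lay, mode = "single_return",
                         seed = 100 + round(10 * tau), ground = c(-5, 0, 0))
    no_hit <- mean(tapply(p$return_index, p$pulse_id, max) == 0)
    p_surv <- exp(-tau)
    se <- sqrt(p_surv * (1 - p_surv) / n)
    expect_lt(abs(no_hit - p_surv), 3 * se + 1e-12)
  }
})

test_that("single-return mode yields at most one vegetation return of fraction 1", {
  g <- homo_grid(0.8, c(8, 8, 8))
  p <- simulate_survey(g, random_bundle(g, 2000, seed = 21), "single_return",
                       seed = 22, ground = c(-10, 0, 0))
  per <- dplyr::count(p[p$return_index > 0 & !p$is_ground, ], pulse_id)
  expect_true(all(per$n <= 1))
  expect_true(all(p$beam_fraction[p$return_index > 0] == 1))
})

test_that("beam fractions are conserved per pulse", {
  g <- homo_grid(0.8, c(8, 8, 8))
  p <- simulate_survey(g, random_bundle(g, 2000, seed = 31), "multi_return",
                       seed = 32, ground = c(-10, 0, 0))
  tot <- tapply(p$beam_fraction, p$pulse_id, sum)
  expect_true(all(tot <= 1 + 1e-9))
  with_ret <- tapply(p$return_index > 0, p$pulse_id, any)
  expect_true(all(abs(tot[with_ret] - 1) < 1e-9))
})

test_that("surveys are reproducible and seed-sensitive", {
  g <- homo_grid(0.5, c(6, 6, 6))
  b <- random_bundle(g, 500, seed = 8)
  p1 <- simulate_survey(g, b, seed = 5)
  p2 <- simulate_survey(g, b, seed = 5)
  p3 <- simulate_survey(g, b, seed = 6)
  expect_identical(p1, p2)
  expect_false(identical(p1$range_m, p3$range_m))
})

test_that("out-of-footprint pulse origins are rejected and counted", {
  g <- homo_grid(0.5, c(5, 5, 5))
  lay <- list(origins = rbind(c(-3, 2, 2), c(2, 2, 2)),
              dirs = rbind(c(1, 0, 0), c(1, 0, 0)), max_range = 50)
  p <- simulate_survey(g, lay, seed = 1, ground = c(-5, 0, 0))
  expect_equal(attr(p, "n_rejected"), 1L)
  expect_true(all(p$pulse_id == 2))
})

test_that("scanner layouts honour spacing and angular resolution", {
  lay <- scanner_layout(footprint = c(20, 10), spacing = 5,
                        angular_resolution = 5000, zenith_range = c(30, 130))
  expect_true(all(lay$positions[, 1] >= 0 & lay$positions[, 1] <= 20))
  d <- canopyphen:::scan_directions(lay)
  expect_equal(max(abs(sqrt(rowSums(d^2)) - 1)), 0, tolerance = 1e-12)
})
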