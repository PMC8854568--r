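# Accumulation bookkeeping and the attenuation estimators.

geom3 <- function() list(origin = c(0, 0, 0), voxel_size = 1, dims = c(3L, 1L, 1L))

test_that("a no-hit pulse contributes full entering weight and survivor path", {
  p <- pulse_row(1L, c(-1, 0.5, 0.5), c(1, 0, 0))
  acc <- accumulate(p, geom3(), max_range = 10)
  expect_equal(as.vector(acc$entering_weight), c(1, 1, 1))
  expect_equal(as.vector(acc$intercepted_weight), c(0, 0, 0))
  expect_equal(as.vector(acc$weighted_survivor_path), c(1, 1, 1))
  expect_equal(as.vector(acc$weighted_free_path), c(0, 0, 0))
})

test_that("a single hit mid-voxel-2 deposits its free path from voxel entry", {
  p <- pulse_row(1L, c(-1, 0.5, 0.5), c(1, 0, 0),
                 tibble::tibble(range = 2.4, fraction = 1, is_ground = FALSE))
  acc <- accumulate(p, geom3(), max_range = 10)
  expect_equal(as.vector(acc$intercepted_weight), c(0, 1, 0))
  # voxel 2 entered at range 2.0; hit at 2.4 -> free path 0.4
  expect_equal(as.vector(acc$weighted_free_path), c(0, 0.4, 0))
  expect_equal(as.vector(acc$weighted_survivor_path), c(1, 0, 0))
  expect_equal(as.vector(acc$entering_weight), c(1, 1, 0))
})

test_that("two-hit pulses split the beam and downweight later voxels", {
  p <- pulse_row(1L, c(-1, 0.5, 0.5), c(1, 0, 0),
                 tibble::tibble(range = c(1.5, 3.5), fraction = c(0.5, 0.5),
                                is_ground = c(FALSE, FALSE)))
  acc <- accumulate(p, geom3(), max_range = 10)
  expect_equal(as.vector(acc$entering_weight), c(1, 0.5, 0.5))
  expect_equal(as.vector(acc$intercepted_weight), c(0.5, 0, 0.5))
  expect_equal(as.vector(acc$weighted_free_path), c(0.5 * 0.5, 0, 0.5 * 0.5))
  # voxel 2 crossed fully by the surviving half
  expect_equal(acc$weighted_survivor_path[2, 1, 1], 0.5)
})

test_that("ground returns censor the path and are excluded from interception", {
  p <- pulse_row(1L, c(-1, 0.5, 0.5), c(1, 0, 0),
                 tibble::tibble(range = 2.5, fraction = 1, is_ground = TRUE))
  acc <- accumulate(p, geom3(), max_range = 10)
  expect_equal(as.vector(acc$intercepted_weight), c(0, 0, 0))
  # survivor path runs to the ground hit, not through it
  expect_equal(as.vector(acc$weighted_survivor_path), c(1, 0.5, 0))
})

test_that("interception weight is conserved over the grid", {
  g <- homo_grid(0.6, c(6, 6, 6))
  p <- simulate_survey(g, random_bundle(g, 4000, seed = 5), "multi_return",
                       seed = 9, ground = c(-10, 0, 0))
  acc <- accumulate(p, g, max_range = 400)
  veg <- p[p$return_index > 0 & !p$is_ground, ]
  expect_equal(sum(acc$intercepted_weight), sum(veg$beam_fraction),
               tolerance = 1e-9)
})

test_that("estimator closed forms follow the sufficient statistics", {
  g <- homo_grid(0.5, c(2, 1, 1))
  # hand-built accumulator: 2 intercepted, 8 m of path in voxel 1
  acc <- structure(list(
    entering_weight = array(c(4, 2), c(2, 1, 1)),
    intercepted_weight = array(c(2, 0), c(2, 1, 1)),
    weighted_free_path = array(c(3, 0), c(2, 1, 1)),
    weighted_survivor_path = array(c(5, 2), c(2, 1, 1)),
    weighted_potential_path = array(c(4, 2), c(2, 1, 1)),
    ray_count = array(c(4L, 2L), c(2, 1, 1)),
    origin = c(0, 0, 0), voxel_size = 1, dims = c(2L, 1L, 1L),
    n_pulses = 4L, skipped_returns = 0L), class = "voxel_accumulator")
  att <- estimate_lambda(acc)
  expect_equal(att$lambda[1, 1, 1], 2 / 8)
  expect_equal(att$lambda[2, 1, 1], 0) # no interceptions -> 0, sampled
  expect_true(all(att$sampled))
  pad <- pad_from_lambda(att)
  expect_equal(pad$values[1, 1, 1], 0.5) # lambda 0.25 / G 0.5
  expect_error(pad_from_lambda(att, G = 0), "G must be")
  # corrupted accumulators are refused
  acc$intercepted_weight[1] <- -1
  expect_error(estimate_lambda(acc), "corrupted")
})

test_that("closed-form MLE equals numeric likelihood maximisation to 1e-8", {
  set.seed(11)
  for (i in 1:100) {
    iw <- runif(1, 0.1, 20)
    path <- runif(1, 0.5, 60)
    closed <- iw / path
    numeric <- oracle_lambda_mle(iw, path)
    expect_lt(abs(closed - numeric) / closed, 1e-8)
  }
})

test_that("unsampled voxels are flagged, never zero-filled", {
  p <- pulse_row(1L, c(-1, 0.5, 0.5), c(1, 0, 0))
  acc <- accumulate(p, list(origin = c(0, 0, 0), voxel_size = 1,
                            dims = c(3L, 3L, 1L)), max_range = 10)
  att <- estimate_lambda(acc)
  expect_equal(sum(att$sampled), 3)
  expect_true(all(is.na(att$lambda[!att$sampled])))
})

test_that("fpl and Beer-Lambert estimators agree on dense homogeneous voxels", {
  # constant within-voxel paths (axis-aligned bundles) so the ratio
  # estimator's path-heterogeneity (Jensen) bias does not confound the check
  g <- homo_grid(0.5, c(6, 6, 6)) # lambda = 0.25
  n <- 30000
  lay <- with_seed(2, list(
    origins = rbind(cbind(1e-9, runif(n / 2, 0, 6), runif(n / 2, 0, 6)),
                    cbind(runif(n / 2, 0, 6), 1e-9, runif(n / 2, 0, 6))),
    dirs = rbind(matrix(rep(c(1, 0, 0), n / 2), ncol = 3, byrow = TRUE),
                 matrix(rep(c(0, 1, 0), n / 2), ncol = 3, byrow = TRUE)),
    max_range = 400))
  p <- simulate_survey(g, lay, mode = "single_return", seed = 3,
                       ground = c(-10, 0, 0))
  acc <- accumulate(p, g, max_range = 400)
  l1 <- estimate_lambda(acc, "fpl_mle")$lambda
  l2 <- estimate_lambda(acc, "beer_lambert")$lambda
  dense <- acc$ray_count > 200
  expect_gt(sum(dense), 100)
  ratio <- l1[dense] / l2[dense]
  expect_lt(abs(median(ratio) - 1), 0.02)
})

test_that("Monte-Carlo G for spherical leaf normals is 1/2", {
  expect_equal(g_spherical(), 0.5)
  mc <- g_spherical("monte_carlo", n = 2e5, seed = 4)
  expect_lt(abs(mc - 0.5), 3 * 0.29 / sqrt(2e5)) # sd(|cos|) ~ 0.29
  mc2 <- g_spherical("monte_carlo", n = 2e5, beam = c(1, 2, -1), seed = 5)
  expect_lt(abs(mc2 - 0.5), 0.005)
})
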