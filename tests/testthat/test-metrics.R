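# DTM, height normalisation, column PAI, change profiles, relative PAI.

flat_ground <- function(z = 2, n = 200, seed = 1) {
  with_seed(seed, tibble::tibble(x = runif(n, 0, 10), y = runif(n, 0, 10),
                                 z = z))
}

test_that("a DTM over coplanar ground points is that plane", {
  dtm <- build_dtm(flat_ground(2), resolution = 0.5)
  expect_true(all(abs(dtm$values - 2) < 1e-9))
})

test_that("a tilted plane is recovered to within a centimetre", {
  g <- flat_ground(0, n = 4000, seed = 2)
  g$z <- 0.01 * g$x
  dtm <- build_dtm(g, resolution = 0.5)
  cx <- dtm$origin[1] + (seq_len(nrow(dtm$values)) - 0.5) * dtm$resolution
  truth <- matrix(0.01 * cx, nrow = nrow(dtm$values), ncol = ncol(dtm$values))
  expect_lt(max(abs(dtm$values - truth)), 0.01)
})

test_that("a single ground point propagates everywhere (degenerate IDW)", {
  dtm <- build_dtm(tibble::tibble(x = 5, y = 5, z = 3.7), resolution = 0.5,
                   extent = c(0, 10, 0, 10))
  expect_equal(as.vector(dtm$values), rep(3.7, length(dtm$values)))
})

test_that("zero ground returns is an explicit error", {
  expect_error(build_dtm(tibble::tibble(x = numeric(), y = numeric(),
                                        z = numeric())), "no ground returns")
})

test_that("height normalisation shifts by the DTM and conserves column mass", {
  v <- array(runif(4 * 4 * 12), c(4, 4, 12))
  g <- pad_grid(v, voxel_size = 1)
  flat0 <- dtm_raster(matrix(0, 8, 8), resolution = 0.5)
  expect_equal(normalize_heights(g, flat0)$values, v)
  flat3 <- dtm_raster(matrix(3, 8, 8), resolution = 0.5)
  out <- normalize_heights(g, flat3)
  expect_equal(out$height_reference, "above_ground")
  expect_equal(out$values[, , 1:9], v[, , 4:12])
  # mass below the shift is exact for columns fully inside the grid
  before <- apply(v[, , 4:12], c(1, 2), sum)
  after <- apply(out$values[, , 1:9], c(1, 2), sum)
  expect_lt(max(abs(before - after)), 1e-12)
})

test_that("column PAI sums strata correctly and is additive", {
  g <- pad_grid(array(0.1, c(5, 4, 30)), voxel_size = 1,
                height_reference = "above_ground")
  pai <- column_pai(g, strata_boundary = 15)
  wide <- tidyr::pivot_wider(pai, names_from = "stratum",
                             values_from = "pai")
  expect_true(all(wide$understory == 1.5))
  expect_true(all(wide$upper_canopy == 1.5))
  expect_true(all(wide$total == 3.0))
  expect_equal(wide$total, wide$understory + wide$upper_canopy)
})

test_that("an empty grid gives zero PAI and unsampled columns are dropped", {
  v <- array(0, c(3, 3, 10))
  s <- array(TRUE, c(3, 3, 10))
  s[1, 1, ] <- FALSE     # fully unsampled column
  s[2, 1, 1:5] <- FALSE  # 50% sampled column
  g <- pad_grid(v, voxel_size = 1, height_reference = "above_ground",
                sampled = s)
  expect_message(pai <- column_pai(g, strata_boundary = 5,
                                   min_sampled_frac = 0.8), "omitted")
  expect_equal(attr(pai, "n_omitted"), 2L)
  expect_true(all(pai$pai == 0))
  expect_false(any(pai$column_x == 0.5 & pai$column_y == 0.5))
})

test_that("the defining change profile yields a 15 m boundary", {
  mk <- function(lo, hi) {
    v <- array(NA_real_, c(4, 4, 30))
    v[, , 1:15] <- lo; v[, , 16:30] <- hi
    pad_grid(v, voxel_size = 1, height_reference = "above_ground")
  }
  a <- mk(0.3, 0.3)
  b <- mk(0.31, 0.29) # +0.01 below 15 m, -0.01 above
  prof <- pad_change_profile(a, b)
  expect_equal(nrow(prof), 30)
  sb <- detect_strata_boundary(prof)
  expect_equal(sb$boundary, 15)
  expect_equal(sb$n_crossings, 1L)
})

test_that("uniformly positive or flat profiles yield a no-boundary result", {
  prof <- tibble::tibble(height = 0.5:29.5, delta_pad = 0.01)
  sb <- detect_strata_boundary(prof)
  expect_true(is.na(sb$boundary))
  flat <- tibble::tibble(height = 0.5:29.5, delta_pad = 0)
  expect_true(is.na(detect_strata_boundary(flat)$boundary))
})

test_that("noisy profiles recover the 15 m boundary within 2 m", {
  err <- vapply(1:100, function(s) {
    delta <- ifelse(0.5:29.5 < 15, 0.01, -0.01) +
      with_seed(s, rnorm(30, 0, 0.005))
    sb <- detect_strata_boundary(tibble::tibble(height = 0.5:29.5,
                                                delta_pad = delta))
    abs(sb$boundary - 15)
  }, numeric(1))
  expect_true(all(is.finite(err)))
  expect_lt(max(err), 2)
})

test_that("relative PAI is 100 at baseline and scales multiplicatively", {
  p <- simulate_pai_panel(quiet_design(), seed = 1)
  rp <- relative_pai(p, baseline_time = sort(unique(p$survey_time))[1])
  base <- rp[rp$survey_time == min(rp$survey_time), ]
  expect_true(all(abs(base$pai_rel - 100) < 1e-9))
  # a stratum scaled to 0.947 x baseline reads 94.7
  d2 <- quiet_design(times = 1:2, seasonal_multipliers = tibble::tibble(
    survey = c(1L, 2L), date = 1:2, stratum = "understory",
    edge_class = "interior", multiplier = c(1, 0.947)))
  p2 <- simulate_pai_panel(d2, seed = 1)
  rp2 <- relative_pai(p2, baseline_time = 1)
  u2 <- rp2[rp2$survey_time == 2 & rp2$stratum == "understory" &
              rp2$edge_class == "interior", ]
  expect_equal(unique(round(u2$pai_rel, 9)), 94.7)
  # the paper-style pairing: a 0.43 decline on a 8.1 baseline is 94.7%
  expect_equal(100 * (8.1 - 0.43) / 8.1, 94.7, tolerance = 1e-3)
})
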