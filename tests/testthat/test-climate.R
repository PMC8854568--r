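# Rainfall accumulation, dry-season classification, microclimate
# simulation and aggregation.

test_that("running sums match the closed forms and the brute-force oracle", {
  s <- tibble::tibble(date = as.Date("2019-01-01") + 0:99, rainfall = 10)
  r <- running_rainfall(s)
  expect_true(all(r$running_sum[!r$partial] == 300))
  expect_equal(sum(r$partial), 29)
  # impulse: 200 mm on one day stays in the window for exactly 30 dates
  s2 <- dplyr::mutate(s, rainfall = ifelse(dplyr::row_number() == 40, 200, 0))
  r2 <- running_rainfall(s2)
  expect_equal(sum(r2$running_sum == 200), 30)
  # random series vs oracle
  for (i in 1:5) {
    x <- with_seed(i, rgamma(200, 0.7, scale = 10))
    s3 <- tibble::tibble(date = as.Date("2019-01-01") + 0:199, rainfall = x)
    expect_equal(running_rainfall(s3, 30)$running_sum,
                 oracle_running_sum(x, 30))
  }
})

test_that("date gaps are an explicit error", {
  s <- tibble::tibble(date = as.Date("2019-01-01") + c(0:10, 12:20),
                      rainfall = 1)
  expect_error(running_rainfall(s), "gap")
})

test_that("constant series classify as all dry or all wet", {
  s <- tibble::tibble(date = as.Date("2019-01-01") + 0:119, rainfall = 5)
  lab <- classify_dry_season(running_rainfall(s)) # 150 mm / 30 d
  expect_true(all(lab$series$season[!lab$series$partial] == "dry"))
  s2 <- dplyr::mutate(s, rainfall = 10)           # 300 mm / 30 d
  lab2 <- classify_dry_season(running_rainfall(s2))
  expect_true(all(lab2$series$season[!lab2$series$partial] == "wet"))
  expect_equal(nrow(lab2$windows), 0)
})

test_that("an injected 4-month low-rain window is recovered within 30 days", {
  cf <- rainfall_config()
  truth <- cf$dry_window
  for (s in 1:10) {
    rain <- simulate_rainfall(cf, seed = s)
    lab <- classify_dry_season(running_rainfall(rain))
    main <- lab$windows[which.max(lab$windows$days), ]
    expect_lt(abs(as.numeric(main$start - truth[1])), 30)
    expect_lt(abs(as.numeric(main$end - truth[2])), 30)
    expect_gt(main$days, 60)
  }
})

test_that("short wet interruptions can be bridged", {
  run <- tibble::tibble(date = as.Date("2019-01-01") + 0:59,
                        rainfall = 0,
                        running_sum = c(rep(100, 20), rep(250, 3),
                                        rep(100, 37)),
                        partial = FALSE)
  unbridged <- classify_dry_season(run)
  expect_equal(nrow(unbridged$windows), 2)
  bridged <- classify_dry_season(run, bridge_days = 7)
  expect_equal(nrow(bridged$windows), 1)
  expect_equal(bridged$windows$days, 60)
})

test_that("daily aggregation takes maxima, means and flags heat days", {
  ts <- seq(as.POSIXct("2019-07-01 00:00", tz = "UTC"),
            as.POSIXct("2019-07-01 23:45", tz = "UTC"), by = 900)
  s <- tibble::tibble(logger_id = "L1", edge_class = "interior",
                      distance_to_edge = 100, timestamp = ts,
                      air_temperature = 30, soil_moisture = 0.3)
  d <- daily_aggregate(s)
  expect_equal(d$tmax, 30)
  expect_equal(d$soil_mean, 0.3)
  expect_false(d$heat_day)
  expect_true(d$complete)
  # one 36 C reading among 96 flips the max and the heat flag
  s$air_temperature[50] <- 36
  d2 <- daily_aggregate(s)
  expect_equal(d2$tmax, 36)
  expect_true(d2$heat_day)
  expect_error(daily_aggregate(dplyr::bind_rows(s, s[1, ])), "duplicated")
})

test_that("aggregating an already-daily series returns it unchanged", {
  days <- as.Date("2019-07-01") + 0:9
  s <- tibble::tibble(logger_id = "L1", edge_class = "edge",
                      distance_to_edge = 5,
                      timestamp = as.POSIXct(paste(days, "12:00"),
                                             tz = "UTC"),
                      air_temperature = 25 + 1:10,
                      soil_moisture = 0.25)
  d <- daily_aggregate(s)
  expect_equal(nrow(d), 10)
  expect_equal(d$tmax, 25 + 1:10)
  expect_true(all(d$complete))
})

test_that("a sinusoidal day peaks at the analytic maximum", {
  ts <- seq(as.POSIXct("2019-07-01 00:00", tz = "UTC"),
            as.POSIXct("2019-07-01 23:45", tz = "UTC"), by = 900)
  h <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  s <- tibble::tibble(logger_id = "L1", edge_class = "edge",
                      distance_to_edge = 1, timestamp = ts,
                      air_temperature = 30 + 5 * cos(2 * pi * (h - 14.5) / 24),
                      soil_moisture = 0.3)
  d <- daily_aggregate(s)
  # discretisation: the 15-min grid contains the 14:30 peak exactly
  expect_equal(d$tmax, 35)
})

test_that("zero edge offset removes the edge-interior contrast in expectation", {
  cf <- microclimate_config(date_range = as.Date(c("2019-07-01",
                                                   "2019-07-21")),
                            n_edge = 4, n_interior = 4,
                            edge_offset_dry = 0, edge_offset_wet = 0)
  m <- simulate_microclimate(cf, seed = 2)
  d <- microclimate_group_summary(daily_aggregate(m))
  diff <- with(tidyr::pivot_wider(d[c("date", "edge_class", "tmax_mean")],
                                  names_from = "edge_class",
                                  values_from = "tmax_mean"),
               edge - interior)
  expect_lt(abs(mean(diff)), 0.5)
})

test_that("a 4 C dry-season offset appears in daily-max differences", {
  cf <- microclimate_config(date_range = as.Date(c("2019-08-01",
                                                   "2019-08-21")),
                            n_edge = 5, n_interior = 5,
                            edge_offset_dry = 4)
  m <- simulate_microclimate(cf, seed = 3)
  d <- microclimate_group_summary(daily_aggregate(m))
  w <- tidyr::pivot_wider(d[c("date", "edge_class", "tmax_mean")],
                          names_from = "edge_class",
                          values_from = "tmax_mean")
  expect_lt(abs(mean(w$edge - w$interior) - 4), 0.5)
})

test_that("interior daily maxima cross 35 C only late in the dry window", {
  cf <- microclimate_config(n_edge = 2, n_interior = 6)
  m <- simulate_microclimate(cf, seed = 4)
  d <- daily_aggregate(m)
  gs <- microclimate_group_summary(d)
  int <- gs[gs$edge_class == "interior", ]
  hot <- int$date[int$tmax_mean >= 35]
  expect_gt(length(hot), 0)
  expect_true(min(hot) > as.Date("2019-08-15"))
})
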