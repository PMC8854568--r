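# Synthetic microclimate and rainfall generators. These emulate the climate
# structure the analyses classify and aggregate: a multi-month window with
# 30-day rainfall below 200 mm, understory air temperature with a diurnal
# cycle and a seasonal peak crossing 35 C late in the dry window, edges
# 3-5 C hotter than interiors during the dry season, and soil moisture
# declining through the dry months.

#' Microclimate simulation configuration
#'
#' @param date_range Length-2 Date vector of logger deployment.
#' @param n_edge,n_interior Logger counts per class.
#' @param edge_distances,interior_distances Distances to the forest margin
#'   (m) recycled over the loggers.
#' @param cadence_min Logging cadence, minutes.
#' @param base_tmax Interior daily-maximum temperature outside the seasonal
#'   peak, degrees C.
#' @param peak_tmax Interior daily-maximum at the seasonal peak, degrees C.
#' @param peak_date,peak_width_days Centre and Gaussian width of the seasonal
#'   temperature peak.
#' @param edge_offset_dry,edge_offset_wet Edge-minus-interior daily-maximum
#'   offset (degrees C) inside and outside the dry window.
#' @param dry_window Length-2 Date vector of the dry season used to ramp the
#'   edge offset and the soil-moisture drawdown.
#' @param diurnal_amplitude Half-range of the within-day temperature cycle,
#'   degrees C.
#' @param soil_wet,soil_dry Volumetric soil moisture (cm^3 cm^-3) at the wet
#'   baseline and the late-dry minimum.
#' @param sd_temp,sd_soil Reading-level noise SDs.
#' @return List of class `microclimate_config`.
#' @export
microclimate_config <- function(date_range = as.Date(c("2019-04-27",
                                                       "2019-10-16")),
                                n_edge = 11, n_interior = 11,
                                edge_distances = c(0, 4, 8, 12, 16, 20, 24,
                                                   28, 32, 36, 39),
                                interior_distances = c(45, 60, 80, 100, 140,
                                                       180, 240, 300, 380,
                                                       460, 520),
                                cadence_min = 15, base_tmax = 30.5,
                                peak_tmax = 35.5,
                                peak_date = as.Date("2019-09-25"),
                                peak_width_days = 35,
                                edge_offset_dry = 4, edge_offset_wet = 1.5,
                                dry_window = as.Date(c("2019-06-15",
                                                       "2019-10-15")),
                                diurnal_amplitude = 5,
                                soil_wet = 0.40, soil_dry = 0.24,
                                sd_temp = 0.6, sd_soil = 0.01) {
  abort_if(soil_wet > 1 || soil_dry < 0, "soil moisture must lie in [0, 1]")
  structure(as.list(environment()), class = "microclimate_config")
}

# smooth 0..1 ramp over the dry window with soft 10-day shoulders
dry_ramp <- function(dates, window, shoulder = 10) {
  d <- as.numeric(dates)
  lo <- as.numeric(window[1]); hi <- as.numeric(window[2])
  up <- stats::plogis((d - lo) / (shoulder / 4))
  down <- stats::plogis((hi - d) / (shoulder / 4))
  up * down
}

#' Simulate understory microclimate logger series
#'
#' Air temperature at 15-min cadence built from a seasonal daily-maximum
#' curve (Gaussian peak on a constant base), a sinusoidal diurnal cycle
#' peaking mid-afternoon, an edge offset that ramps from its wet-season to
#' its dry-season value across the configured dry window, and reading noise.
#' Soil moisture declines from the wet baseline to the dry minimum through
#' the window. Reproducible given `seed`.
#'
#' @param config A [microclimate_config()].
#' @param seed Integer seed.
#' @return Tibble: `logger_id`, `edge_class`, `distance_to_edge`,
#'   `timestamp` (UTC POSIXct), `air_temperature` (C), `soil_moisture`
#'   (cm^3 cm^-3).
#' @export
simulate_microclimate <- function(config = microclimate_config(), seed = 1L) {
  stopifnot(inherits(config, "microclimate_config"))
  cf <- config
  loggers <- tibble::tibble(
    logger_id = sprintf("L%02d", seq_len(cf$n_edge + cf$n_interior)),
    edge_class = rep(c("edge", "interior"), c(cf$n_edge, cf$n_interior)),
    distance_to_edge = c(rep_len(cf$edge_distances, cf$n_edge),
                         rep_len(cf$interior_distances, cf$n_interior)))
  times <- seq(as.POSIXct(paste(cf$date_range[1], "00:00"), tz = "UTC"),
               as.POSIXct(paste(cf$date_range[2], "23:59"), tz = "UTC"),
               by = cf$cadence_min * 60)
  dates <- as.Date(times, tz = "UTC")
  hours <- as.numeric(format(times, "%H")) +
    as.numeric(format(times, "%M")) / 60

  peak <- exp(-((as.numeric(dates) - as.numeric(cf$peak_date)) /
                  cf$peak_width_days)^2)
  tmax_interior <- cf$base_tmax + (cf$peak_tmax - cf$base_tmax) * peak
  ramp <- dry_ramp(dates, cf$dry_window)
  offset <- cf$edge_offset_wet + (cf$edge_offset_dry - cf$edge_offset_wet) * ramp
  # diurnal cycle peaking at 14:30, so daily max equals the target curve
  diurnal <- cf$diurnal_amplitude * (cos(2 * pi * (hours - 14.5) / 24) - 1)
  soil <- cf$soil_wet - (cf$soil_wet - cf$soil_dry) * ramp

  with_seed(seed, purrr::pmap_dfr(loggers, function(logger_id, edge_class,
                                                    distance_to_edge) {
    off <- if (edge_class == "edge") offset else 0
    tibble::tibble(
      logger_id = logger_id, edge_class = edge_class,
      distance_to_edge = distance_to_edge, timestamp = times,
      air_temperature = tmax_interior + off + diurnal +
        rnorm(length(times), 0, cf$sd_temp),
      soil_moisture = pmin(pmax(
        soil + rnorm(length(times), 0, cf$sd_soil), 0), 1))
  }))
}

#' Rainfall simulation configuration
#'
#' @param date_range Length-2 Date vector.
#' @param dry_window Length-2 Date vector of the low-rain window (default
#'   four months, mid-June to mid-October).
#' @param wet_mean,dry_mean Mean daily rainfall (mm) outside/inside the
#'   window.
#' @param shape Gamma shape of daily rainfall.
#' @param transition_days Length of the linear ramp between regimes.
#' @return List of class `rainfall_config`.
#' @export
rainfall_config <- function(date_range = as.Date(c("2019-03-01",
                                                   "2019-11-30")),
                            dry_window = as.Date(c("2019-06-15",
                                                   "2019-10-15")),
                            wet_mean = 10.5, dry_mean = 3.2, shape = 1.2,
                            transition_days = 10) {
  structure(as.list(environment()), class = "rainfall_config")
}

#' Simulate a daily rainfall series
#'
#' Gamma-distributed daily totals whose mean ramps from a wet-season level
#' (30-day sums well above 200 mm) down to a dry-window level (30-day sums
#' well below 200 mm) and back, so the trailing 30-day sum drops below the
#' 200 mm threshold for approximately the configured window.
#'
#' @param config A [rainfall_config()].
#' @param seed Integer seed.
#' @return Tibble: `date`, `rainfall` (mm/day).
#' @export
simulate_rainfall <- function(config = rainfall_config(), seed = 1L) {
  stopifnot(inherits(config, "rainfall_config"))
  cf <- config
  dates <- seq(cf$date_range[1], cf$date_range[2], by = "day")
  ramp <- dry_ramp(dates, cf$dry_window, shoulder = cf$transition_days)
  mu <- cf$wet_mean - (cf$wet_mean - cf$dry_mean) * ramp
  rain <- with_seed(seed,
                    rgamma(length(dates), shape = cf$shape,
                           scale = mu / cf$shape))
  tibble::tibble(date = dates, rainfall = rain)
}
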