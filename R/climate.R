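# Climate analysis: trailing-window rainfall accumulation, dry-season
# classification, and aggregation of sub-daily microclimate readings to the
# daily summaries (daily maximum temperature, mean soil moisture) that are
# read against the PAI time-series.

#' Trailing running rainfall sum
#'
#' Accumulated rainfall over the trailing `window` days, aligned to the
#' window end. The first `window - 1` dates are flagged `partial`. Gaps in
#' the date sequence are an explicit error: fill or declare them first, no
#' silent interpolation.
#'
#' @param series Tibble with `date` (Date, consecutive) and `rainfall`
#'   (mm/day, >= 0).
#' @param window Window length, days.
#' @return The series with `running_sum` (mm) and `partial` columns.
#' @export
running_rainfall <- function(series, window = 30) {
  abort_if(!all(c("date", "rainfall") %in% names(series)),
           "series needs `date` and `rainfall` columns")
  abort_if(any(series$rainfall < 0, na.rm = TRUE), "rainfall must be >= 0")
  d <- as.numeric(series$date)
  abort_if(any(diff(d) != 1),
           "gap in the date sequence; fill missing dates explicitly")
  r <- series$rainfall
  cs <- cumsum(r)
  n <- length(r)
  run <- cs - c(rep(0, min(window, n)), head(cs, max(0, n - window)))
  dplyr::mutate(series, running_sum = run,
                partial = dplyr::row_number() < window)
}

#' Classify the dry season from running rainfall
#'
#' A date is dry when its trailing `window`-day rainfall sum is below
#' `threshold` (default 200 mm / 30 days). Wet interruptions shorter than
#' `bridge_days` can optionally be bridged into the surrounding dry spell
#' (off by default). Partial-window dates are left unlabelled.
#'
#' @param running Output of [running_rainfall()] (or a series; the running
#'   sum is computed with `window`).
#' @param threshold Dry threshold, mm per window.
#' @param window Window length used if `running_sum` is absent.
#' @param bridge_days Bridge wet gaps shorter than this many days (0 = off).
#' @return Object of class `season_labels`: the labelled series plus a
#'   `windows` tibble of contiguous dry spells (`start`, `end`, `days`).
#' @export
classify_dry_season <- function(running, threshold = 200, window = 30,
                                bridge_days = 0) {
  if (!"running_sum" %in% names(running))
    running <- running_rainfall(running, window)
  abort_if(all(running$partial), "all dates are partial-window: series too short")
  lab <- ifelse(running$partial, NA_character_,
                ifelse(running$running_sum < threshold, "dry", "wet"))
  if (bridge_days > 0) {
    r <- rle(lab)
    short_wet <- which(r$values == "wet" & r$lengths < bridge_days)
    inner <- short_wet[short_wet > 1 & short_wet < length(r$values)]
    keep <- inner[r$values[inner - 1] == "dry" & r$values[inner + 1] == "dry"]
    r$values[keep] <- "dry"
    lab <- inverse.rle(r)
  }
  out <- dplyr::mutate(running, season = lab)
  dry <- !is.na(lab) & lab == "dry"
  r <- rle(dry)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  windows <- tibble::tibble(start = out$date[starts[r$values]],
                            end = out$date[ends[r$values]]) |>
    dplyr::mutate(days = as.numeric(.data$end - .data$start) + 1)
  structure(list(series = out, windows = windows, threshold = threshold,
                 window = window), class = "season_labels")
}

#' @export
print.season_labels <- function(x, ...) {
  cat(sprintf("<season_labels> threshold %g mm / %d days; %d dry spell(s)\n",
              x$threshold, x$window, nrow(x$windows)))
  if (nrow(x$windows) > 0) print(x$windows)
  invisible(x)
}

#' Aggregate sub-daily microclimate readings to daily summaries
#'
#' Per logger and date: maximum air temperature, mean soil moisture, and a
#' heat-day flag (daily maximum at or above `heat_threshold`). The expected
#' readings per day are inferred from each logger's median cadence, and days
#' with less than `min_coverage` of them are flagged incomplete (kept, not
#' dropped). Duplicated timestamps within a logger are an error.
#'
#' @param series Tibble with `logger_id`, `edge_class`, `timestamp`,
#'   `air_temperature`, `soil_moisture` (see [simulate_microclimate()]).
#' @param min_coverage Minimum fraction of expected readings for a complete
#'   day.
#' @param heat_threshold Heat-day temperature threshold, degrees C.
#' @return Tibble: `logger_id`, `edge_class`, `distance_to_edge`, `date`,
#'   `tmax` (C), `soil_mean`, `n_readings`, `complete`, `heat_day`.
#' @export
daily_aggregate <- function(series, min_coverage = 0.75, heat_threshold = 35) {
  abort_if(anyDuplicated(series[c("logger_id", "timestamp")]) > 0,
           "duplicated timestamps within a logger")
  cadence <- series |>
    dplyr::group_by(.data$logger_id) |>
    dplyr::summarise(step = {
      dt <- diff(sort(unique(as.numeric(.data$timestamp))))
      if (length(dt) == 0) 86400 else median(dt)
    }, .groups = "drop") |>
    dplyr::mutate(expected = pmax(1, round(86400 / .data$step)))
  series |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$logger_id, .data$edge_class,
                    dplyr::across(dplyr::any_of("distance_to_edge")),
                    .data$date) |>
    dplyr::summarise(tmax = max(.data$air_temperature),
                     soil_mean = mean(.data$soil_moisture),
                     n_readings = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(cadence[c("logger_id", "expected")], by = "logger_id") |>
    dplyr::mutate(complete = .data$n_readings >= min_coverage * .data$expected,
                  heat_day = .data$tmax >= heat_threshold) |>
    dplyr::select(-"expected")
}

#' Edge/interior group summary of daily microclimate
#'
#' Group means with across-logger standard errors, per date and edge class.
#'
#' @param daily Output of [daily_aggregate()].
#' @param complete_only Use complete days only.
#' @return Tibble: `date`, `edge_class`, `tmax_mean`, `tmax_se`,
#'   `soil_mean`, `soil_se`, `n_loggers`.
#' @export
microclimate_group_summary <- function(daily, complete_only = TRUE) {
  if (complete_only) daily <- daily[daily$complete, ]
  daily |>
    dplyr::group_by(.data$date, .data$edge_class) |>
    dplyr::summarise(tmax_mean = mean(.data$tmax),
                     tmax_se = sd(.data$tmax) / sqrt(dplyr::n()),
                     soil_mean = mean(.data$soil_mean),
                     soil_se = sd(.data$soil_mean) / sqrt(dplyr::n()),
                     n_loggers = dplyr::n(), .groups = "drop")
}
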