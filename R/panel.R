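# Direct simulation of PAI panels (long-format survey x column x stratum
# tables) with a known fixed-effect structure, transect and edge-within-
# transect random intercepts, and optionally heteroscedastic residual noise.
# This bypasses ray tracing so the edge and phenology models can be tested
# for parameter recovery at scale.

#' Panel design for direct PAI simulation
#'
#' Defaults emulate the study layout: two 100 m transects running inland from
#' the fragment margin (so each contributes edge and interior columns) and
#' one 30 m interior transect 500 m from any margin; eleven fortnightly
#' surveys April--October; baseline interior PAI 8.1 (understory) + 3.3
#' (upper canopy) m^2 m^-2; an asymptotic distance-to-edge gradient; and the
#' seasonal trajectories of [default_seasonal_multipliers()].
#'
#' @param times Vector of survey times (dates or indices).
#' @param transects Tibble with `transect_id`, `x_min`, `x_max` (distance to
#'   edge range covered by the transect's columns, metres).
#' @param column_spacing Distance between simulated columns, metres.
#' @param baseline Named numeric: baseline stratum PAI at the interior
#'   asymptote (`understory`, `upper_canopy`).
#' @param edge_profile `"asymptotic"` (multiplier from `edge_gradient`),
#'   `"hockey"` (piecewise-linear in distance with break `hockey_break` and
#'   slope `hockey_slope` below it), or `"none"`.
#' @param edge_gradient `c(beta0, beta1, beta2)` of the asymptotic PAI curve;
#'   `beta0` should equal the total baseline for the curve to be exact.
#' @param hockey_break,hockey_slope Piecewise profile: total PAI equals the
#'   baseline beyond the break and drops linearly by `hockey_slope` (m^2 m^-2
#'   per m) below it.
#' @param seasonal_multipliers Tibble as [default_seasonal_multipliers()]
#'   (matched to `times` by position via its `survey` index), or `NULL` for
#'   no seasonality.
#' @param cell_effects Optional tibble (`survey`, `edge_class`, `stratum`,
#'   `delta`) of additive injections into specific design cells.
#' @param edge_threshold Edge/interior split, metres.
#' @param sd_transect,sd_edge_within Random-intercept SDs per stratum.
#' @param sd_resid Residual SD; scalar or named by edge class
#'   (`c(edge = ..., interior = ...)`) for heteroscedastic noise.
#' @return A list of class `panel_design`.
#' @export
panel_design <- function(times = default_seasonal_multipliers()$date[1:11],
                         transects = tibble::tibble(
                           transect_id = c("T1", "T2", "T3"),
                           x_min = c(0, 0, 500), x_max = c(100, 100, 530)),
                         column_spacing = 2,
                         baseline = c(understory = 8.1, upper_canopy = 3.3),
                         edge_profile = c("asymptotic", "hockey", "none"),
                         edge_gradient = c(beta0 = 11.4, beta1 = -1.7,
                                           beta2 = 0.08),
                         hockey_break = 37, hockey_slope = 0.046,
                         seasonal_multipliers = default_seasonal_multipliers(),
                         cell_effects = NULL, edge_threshold = 40,
                         sd_transect = 0.25, sd_edge_within = 0.12,
                         sd_resid = c(edge = 0.45, interior = 0.35)) {
  edge_profile <- match.arg(edge_profile)
  abort_if(length(unique(times)) < 2 && !is.null(seasonal_multipliers),
           "need >= 2 survey times (or set seasonal_multipliers = NULL)")
  abort_if(nrow(transects) < 2, "need >= 2 transects")
  abort_if(any(c(sd_transect, sd_edge_within, sd_resid) < 0),
           "SDs must be >= 0")
  structure(list(times = times, transects = transects,
                 column_spacing = column_spacing, baseline = baseline,
                 edge_profile = edge_profile, edge_gradient = edge_gradient,
                 hockey_break = hockey_break, hockey_slope = hockey_slope,
                 seasonal_multipliers = seasonal_multipliers,
                 cell_effects = cell_effects, edge_threshold = edge_threshold,
                 sd_transect = sd_transect, sd_edge_within = sd_edge_within,
                 sd_resid = sd_resid),
            class = "panel_design")
}

#' Simulate a PAI panel with known truth
#'
#' Builds deterministic cell means (baseline x edge profile x seasonal
#' multiplier + injected cell effects), adds per-stratum transect and
#' edge-within-transect random intercepts and heteroscedastic residual noise,
#' and emits understory, upper canopy and total rows (total is the exact sum
#' of the two stratum draws, so column additivity holds row-wise). The truth
#' (noise-free cell means and the design) is attached as attributes.
#'
#' @param design A [panel_design()].
#' @param seed Integer seed; identical seed and design give an identical
#'   panel.
#' @return PAI panel tibble: `column_id`, `column_x`, `column_y`,
#'   `transect_id`, `distance_to_edge`, `edge_class`, `survey_time`, `time`
#'   (factor), `stratum`, `pai`; truth in `attr(, "truth")`.
#' @export
simulate_pai_panel <- function(design = panel_design(), seed = 1L) {
  stopifnot(inherits(design, "panel_design"))
  d <- design
  cols <- purrr::pmap_dfr(d$transects, function(transect_id, x_min, x_max) {
    x <- seq(x_min, x_max, by = d$column_spacing)
    tibble::tibble(transect_id = transect_id, column_x = x, column_y = 0,
                   distance_to_edge = x)
  })
  cols$column_id <- paste0(cols$transect_id, "_", seq_len(nrow(cols)))
  cols$edge_class <- classify_edge(cols$distance_to_edge, d$edge_threshold)

  edge_mult <- switch(d$edge_profile,
    asymptotic = edge_multiplier(cols$distance_to_edge, d$edge_gradient),
    hockey = 1 - d$hockey_slope *
      pmax(d$hockey_break - cols$distance_to_edge, 0) / sum(d$baseline),
    none = rep(1, nrow(cols)))

  times <- tibble::tibble(survey = seq_along(d$times), survey_time = d$times)
  strata <- names(d$baseline)

  grid <- tidyr::expand_grid(cols, times, stratum = strata)
  grid$mu <- d$baseline[grid$stratum] *
    edge_mult[match(grid$column_id, cols$column_id)]
  if (!is.null(d$seasonal_multipliers)) {
    sm <- d$seasonal_multipliers
    key <- paste(grid$survey, grid$stratum, grid$edge_class)
    smk <- paste(sm$survey, sm$stratum, sm$edge_class)
    m <- sm$multiplier[match(key, smk)]
    m[is.na(m)] <- 1
    grid$mu <- grid$mu * m
  }
  if (!is.null(d$cell_effects)) {
    ce <- d$cell_effects
    key <- paste(grid$survey, grid$edge_class, grid$stratum)
    cek <- paste(ce$survey, ce$edge_class, ce$stratum)
    delta <- ce$delta[match(key, cek)]
    grid$mu <- grid$mu + ifelse(is.na(delta), 0, delta)
  }

  sdr <- d$sd_resid
  if (is.null(names(sdr))) sdr <- c(edge = unname(sdr[1]),
                                    interior = unname(sdr[1]))
  panel <- with_seed(seed, {
    tr_levels <- unique(grid$transect_id)
    u_tr <- matrix(rnorm(length(tr_levels) * length(strata), 0, d$sd_transect),
                   nrow = length(tr_levels),
                   dimnames = list(tr_levels, strata))
    ge_levels <- unique(paste(grid$transect_id, grid$edge_class))
    u_ge <- matrix(rnorm(length(ge_levels) * length(strata), 0,
                         d$sd_edge_within),
                   nrow = length(ge_levels),
                   dimnames = list(ge_levels, strata))
    grid$pai <- grid$mu +
      u_tr[cbind(grid$transect_id, grid$stratum)] +
      u_ge[cbind(paste(grid$transect_id, grid$edge_class), grid$stratum)] +
      rnorm(nrow(grid), 0, sdr[grid$edge_class])
    grid
  })
  panel$pai <- pmax(panel$pai, 0)

  total <- panel |>
    dplyr::group_by(dplyr::across(c("column_id", "column_x", "column_y",
                                    "transect_id", "distance_to_edge",
                                    "edge_class", "survey", "survey_time"))) |>
    dplyr::summarise(stratum = "total", mu = sum(.data$mu),
                     pai = sum(.data$pai), .groups = "drop")
  out <- dplyr::bind_rows(panel, total) |>
    dplyr::mutate(time = factor(.data$survey,
                                labels = as.character(sort(unique(d$times))))) |>
    dplyr::arrange(.data$survey, .data$transect_id, .data$column_x,
                   .data$stratum) |>
    dplyr::select("column_id", "column_x", "column_y", "transect_id",
                  "distance_to_edge", "edge_class", "survey", "survey_time",
                  "time", "stratum", "pai", "mu")
  truth <- list(design = d,
                cell_means = out |>
                  dplyr::distinct(.data$survey, .data$survey_time,
                                  .data$edge_class, .data$stratum,
                                  .data$distance_to_edge, .data$mu))
  names(out)[names(out) == "mu"] <- "pai_truth"
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  out
}
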