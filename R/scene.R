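# Synthetic-forest truth scenes. The generator emulates the structure the
# downstream analyses assume: a two-stratum vertical profile split near 15 m
# above ground, an asymptotic edge-to-interior gradient in column PAI, and
# survey-to-survey multiplicative seasonal anomalies of a few percent per
# stratum and edge class.

#' Default per-survey seasonal PAD multipliers
#'
#' Eleven survey dates spanning April--October (fortnightly, with a 40-day gap
#' between late April and early June) and, for each stratum x edge-class cell,
#' the multiplicative anomaly of PAD relative to the first survey. The default
#' trajectories emulate the field-scale effect sizes this package is designed
#' to recover: an interior understory decline bottoming out at -5.3% in late
#' July, recovering fully by September and greening up slightly beyond
#' baseline as the upper canopy sheds; an interior upper canopy that is
#' stable (a slight mid-season flush) before dropping to -7.6% by the final
#' (mid-October) survey, so interior survey means of the two strata are
#' strongly negatively coupled (R^2 ~ 0.8); an edge understory with a mild
#' (-3.4%) aseasonal deficit from July onwards; and an edge upper canopy
#' losing ~6% by mid-July, persisting through the dry season.
#'
#' @return A tibble with columns `survey`, `date`, `stratum`, `edge_class`,
#'   `multiplier`.
#' @export
default_seasonal_multipliers <- function() {
  dates <- as.Date(c("2019-04-11", "2019-04-26", "2019-06-05", "2019-06-24",
                     "2019-07-09", "2019-07-24", "2019-08-08", "2019-08-23",
                     "2019-09-07", "2019-09-22", "2019-10-16"))
  traj <- list(
    understory.interior   = c(1, .980, .958, .950, .948, .947, .960, .980,
                              1.004, 1.016, 1.028),
    upper_canopy.interior = c(1, 1.010, 1.017, 1.019, 1.020, 1.021, 1.013,
                              1.000, .984, .954, .924),
    understory.edge       = c(1, .992, .978, .972, .966, .966, .968, .970,
                              .972, .970, .968),
    upper_canopy.edge     = c(1, .990, .970, .955, .945, .940, .936, .932,
                              .928, .922, .916)
  )
  purrr::imap_dfr(traj, function(m, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    tibble::tibble(survey = seq_along(dates), date = dates,
                   stratum = parts[1], edge_class = parts[2], multiplier = m)
  })
}

#' Configuration of a synthetic forest scene
#'
#' Defines the voxelised truth PAD field from which TLS surveys are
#' simulated. Defaults mirror the emulated study layout: a 100 x 10 m
#' transect footprint with a 35 m canopy, a 15 m strata boundary, stratum PAD
#' means giving a baseline interior column PAI of 8.1 (understory) + 3.3
#' (upper canopy) = 11.4 m^2 m^-2, and an asymptotic edge gradient
#' `beta0 + beta1 * exp(-beta2 * x)` in column PAI with the interior asymptote
#' `beta0` matching that baseline.
#'
#' @param extent Numeric length-3 scene extent (x, y, z), metres. The x axis
#'   is the distance-to-edge axis; the edge is the plane x = 0.
#' @param voxel_size Voxel edge length, metres.
#' @param ground Parameters `c(elevation, slope_x, slope_y)` of the smooth
#'   analytic ground surface z = elevation + slope_x * x + slope_y * y.
#' @param strata_boundary Height (m, above ground) splitting understory from
#'   upper canopy.
#' @param understory_pad_mean,canopy_pad_mean Baseline (interior, first
#'   survey) stratum PAD means, m^2 m^-3.
#' @param edge_gradient Named or positional numeric `c(beta0, beta1, beta2)`
#'   of the asymptotic distance-to-edge PAI curve; applied to PAD as the
#'   dimensionless multiplier `(beta0 + beta1 exp(-beta2 x)) / beta0`.
#' @param seasonal_multipliers Tibble as in
#'   [default_seasonal_multipliers()].
#' @param edge_threshold Distance (m) below which a column counts as edge when
#'   looking up seasonal multipliers.
#' @param heterogeneity_cv Coefficient of variation of the per-voxel lognormal
#'   heterogeneity multiplier (mean 1); 0 disables it.
#' @param seed Integer seed making every derived truth grid deterministic.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(extent = c(100, 10, 35), voxel_size = 1,
                         ground = c(0, 0, 0), strata_boundary = 15,
                         understory_pad_mean = 0.54, canopy_pad_mean = 0.165,
                         edge_gradient = c(beta0 = 11.4, beta1 = -1.7,
                                           beta2 = 0.08),
                         seasonal_multipliers = default_seasonal_multipliers(),
                         edge_threshold = 40, heterogeneity_cv = 0.3,
                         seed = 1L) {
  abort_if(voxel_size <= 0, "voxel_size must be > 0")
  abort_if(understory_pad_mean <= 0 || canopy_pad_mean <= 0,
           "stratum PAD means must be > 0")
  abort_if(strata_boundary <= 0 || strata_boundary >= extent[3],
           "strata_boundary must lie inside (0, extent_z)")
  abort_if(any(seasonal_multipliers$multiplier <= 0),
           "seasonal multipliers must be > 0")
  abort_if(any(extent %% voxel_size > 1e-9 &
                 voxel_size - extent %% voxel_size > 1e-9),
           "extents must be whole multiples of voxel_size")
  eg <- unname(as.numeric(edge_gradient))
  structure(list(extent = as.numeric(extent), voxel_size = voxel_size,
                 ground = as.numeric(ground),
                 strata_boundary = strata_boundary,
                 understory_pad_mean = understory_pad_mean,
                 canopy_pad_mean = canopy_pad_mean,
                 edge_gradient = c(beta0 = eg[1], beta1 = eg[2],
                                   beta2 = eg[3]),
                 seasonal_multipliers = seasonal_multipliers,
                 edge_threshold = edge_threshold,
                 heterogeneity_cv = heterogeneity_cv,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Asymptotic edge multiplier
#'
#' Dimensionless multiplier `(beta0 + beta1 * exp(-beta2 * x)) / beta0`
#' applied to baseline PAD at distance-to-edge `x`; approaches 1 in the
#' interior, so when the baseline column PAI equals `beta0` the resulting
#' PAI-versus-distance curve is exactly `beta0 + beta1 exp(-beta2 x)`.
#'
#' @param x Distance to edge, metres.
#' @param edge_gradient Numeric `c(beta0, beta1, beta2)`.
#' @return Multiplier values.
#' @export
edge_multiplier <- function(x, edge_gradient) {
  b <- as.numeric(edge_gradient)
  (b[1] + b[2] * exp(-b[3] * x)) / b[1]
}

ground_elevation <- function(config, x, y) {
  g <- config$ground
  g[1] + g[2] * x + g[3] * y
}

#' Build a truth PAD grid for one survey
#'
#' PAD(voxel) = stratum mean x edge multiplier(distance to edge) x seasonal
#' multiplier(survey, stratum, edge class) x optional lognormal heterogeneity.
#' Voxels below the ground surface get PAD 0. Deterministic given the config
#' seed and survey index.
#'
#' @param config A [scene_config()].
#' @param survey Survey index into the configured seasonal multipliers.
#' @return A [pad_grid()] with absolute height reference.
#' @export
build_truth_grid <- function(config, survey = 1L) {
  stopifnot(inherits(config, "scene_config"))
  sm <- config$seasonal_multipliers
  abort_if(!survey %in% sm$survey, "survey index not in seasonal_multipliers")
  v <- config$voxel_size
  d <- as.integer(round(config$extent / v))
  xc <- (seq_len(d[1]) - 0.5) * v
  yc <- (seq_len(d[2]) - 0.5) * v
  zc <- (seq_len(d[3]) - 0.5) * v

  smx <- sm[sm$survey == survey, ]
  mult <- function(stratum, edge_class) {
    m <- smx$multiplier[smx$stratum == stratum & smx$edge_class == edge_class]
    if (length(m) == 0) 1 else m[1]
  }

  vals <- array(0, d)
  em <- edge_multiplier(xc, config$edge_gradient)
  edge_cls <- ifelse(xc < config$edge_threshold, "edge", "interior")
  for (i in seq_len(d[1])) {
    gz <- ground_elevation(config, xc[i], yc) # length ny
    for (j in seq_len(d[2])) {
      h <- zc - gz[j]                         # height above ground
      base <- ifelse(h < 0, 0,
                     ifelse(h < config$strata_boundary,
                            config$understory_pad_mean,
                            config$canopy_pad_mean))
      strat <- ifelse(h < config$strata_boundary, "understory", "upper_canopy")
      mm <- vapply(strat, mult, numeric(1), edge_class = edge_cls[i])
      vals[i, j, ] <- base * em[i] * mm
    }
  }
  if (config$heterogeneity_cv > 0) {
    sdlog <- sqrt(log(1 + config$heterogeneity_cv^2))
    noise <- with_seed(derive_seed(config$seed, paste0("truth", survey)),
                       rlnorm(prod(d), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    vals <- vals * array(noise, d)
  }
  pad_grid(vals, origin = c(0, 0, 0), voxel_size = v,
           height_reference = "absolute",
           provenance = list(kind = "truth", survey = survey,
                             seed = config$seed))
}
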