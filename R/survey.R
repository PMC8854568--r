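# TLS survey simulation: pulse generation from a scanner layout, exact ray
# tracing through the truth grid, and exponential free-path sampling of
# interceptions (the generative model inverted downstream by the estimator).

#' Scanner layout
#'
#' Scan positions plus angular sampling of the instrument. Defaults follow a
#' field protocol of scans every 5 m in three parallel lines, 40 mdeg angular
#' steps, a 30--130 degree zenith window completed by a tilted companion scan,
#' a 350 m range and up to eight returns per pulse. For desk-scale simulation
#' the angular resolution is the knob to coarsen: the pulse count scales with
#' its inverse square.
#'
#' @param positions Matrix or data frame of scan positions (x, y, z in m). If
#'   `NULL`, a grid of three lines spaced `spacing` apart covering
#'   `footprint` is generated at height `scanner_height`.
#' @param footprint Length-2 (x, y) extent used when auto-placing positions.
#' @param spacing Scan spacing along and between lines, metres.
#' @param scanner_height Instrument height above z = 0, metres.
#' @param angular_resolution Angular step, milli-degrees.
#' @param zenith_range Zenith window of the upright scan, degrees.
#' @param tilted Add a companion scan tilted 90 degrees so the full sphere is
#'   sampled.
#' @param max_range Maximum measurement range, metres.
#' @param max_returns Maximum returns per pulse.
#' @return A list of class `scanner_layout`.
#' @export
scanner_layout <- function(positions = NULL, footprint = c(100, 10),
                           spacing = 5, scanner_height = 1.3,
                           angular_resolution = 40,
                           zenith_range = c(30, 130), tilted = TRUE,
                           max_range = 350, max_returns = 8L) {
  abort_if(angular_resolution <= 0, "angular_resolution must be > 0")
  abort_if(max_returns < 1, "max_returns must be >= 1")
  if (is.null(positions)) {
    xs <- seq(spacing / 2, footprint[1] - spacing / 2, by = spacing)
    ys <- seq(spacing / 2, footprint[2] - spacing / 2,
              length.out = min(3, max(1, floor(footprint[2] / spacing))))
    positions <- as.matrix(expand.grid(x = xs, y = ys))
    positions <- cbind(positions, z = scanner_height)
  }
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  structure(list(positions = positions, spacing = spacing,
                 angular_resolution = angular_resolution,
                 zenith_range = zenith_range, tilted = tilted,
                 max_range = max_range, max_returns = as.integer(max_returns)),
            class = "scanner_layout")
}

# Unit directions of one scan: zenith measured from `axis`, azimuth swept
# fully, both stepped at the layout's angular resolution.
scan_directions <- function(layout) {
  step <- layout$angular_resolution / 1000 # degrees
  zen <- seq(layout$zenith_range[1], layout$zenith_range[2], by = step)
  azi <- seq(0, 360 - step, by = step)
  grid <- expand.grid(zen = zen * pi / 180, azi = azi * pi / 180)
  up <- cbind(sin(grid$zen) * cos(grid$azi),
              sin(grid$zen) * sin(grid$azi),
              cos(grid$zen))
  if (!layout$tilted) return(up)
  # companion scan with the zenith axis rotated onto +x
  tilt <- cbind(cos(grid$zen),
                sin(grid$zen) * cos(grid$azi),
                sin(grid$zen) * sin(grid$azi))
  rbind(up, tilt)
}

#' Simulate a TLS survey through a truth PAD grid
#'
#' For every pulse a target optical depth `tau* = -log(U)` is drawn; the pulse
#' is walked through the voxel grid accumulating `PAD x G x segment length`
#' and a vegetation hit is recorded where the accumulated depth reaches
#' `tau*`. In `multi_return` mode the beam continues past each hit with
#' probability `p_continue` (up to the layout's `max_returns`), drawing a
#' fresh target depth each time; recorded returns then share the beam section
#' equally (fraction `1/k` each, the equal-split assumption of the
#' estimator). A pulse not intercepted before reaching the analytic ground
#' surface gets a terminal ground return; a pulse that exits the scene or
#' exceeds `max_range` without any return is kept as a marker row
#' (`return_index = 0`) so that its survivor path still informs estimation.
#'
#' @param grid Truth [pad_grid()] (absolute heights).
#' @param layout A [scanner_layout()], or a list with `origins` and `dirs`
#'   matrices for fully custom pulse sets.
#' @param mode `"single_return"` or `"multi_return"`.
#' @param seed Integer seed; identical seeds and inputs give byte-identical
#'   pulse sets.
#' @param G Projection-function constant converting PAD to attenuation.
#' @param p_continue Continuation probability past a recorded hit
#'   (multi-return mode).
#' @param ground Ground plane coefficients `c(elevation, slope_x, slope_y)`.
#' @return A tibble of pulse records (one row per return, plus marker rows
#'   for no-return pulses): `pulse_id`, `ox, oy, oz`, `dx, dy, dz`,
#'   `return_index`, `range_m`, `beam_fraction`, `is_ground`. The number of
#'   rejected out-of-footprint pulses is in `attr(, "n_rejected")`.
#' @export
simulate_survey <- function(grid, layout, mode = c("multi_return",
                                                   "single_return"),
                            seed = 1L, G = 0.5, p_continue = 0.5,
                            ground = c(0, 0, 0)) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "pad_grid"))
  if (inherits(layout, "scanner_layout")) {
    dirs0 <- scan_directions(layout)
    npos <- nrow(layout$positions)
    origins <- layout$positions[rep(seq_len(npos), each = nrow(dirs0)), ,
                                drop = FALSE]
    dirs <- dirs0[rep(seq_len(nrow(dirs0)), times = npos), , drop = FALSE]
    max_range <- layout$max_range
    max_returns <- layout$max_returns
  } else {
    origins <- as.matrix(layout$origins)
    dirs <- as.matrix(layout$dirs)
    max_range <- layout$max_range %||% 350
    max_returns <- layout$max_returns %||% 8L
  }
  stopifnot(nrow(origins) == nrow(dirs))
  dirs <- dirs / sqrt(rowSums(dirs^2))

  lam <- grid$values * G
  res <- with_seed(seed, cpp_simulate_pulses(
    origins, dirs, as.numeric(lam), grid$origin, grid$voxel_size,
    dim(grid$values), max_range,
    ifelse(mode == "single_return", 1L, 2L), p_continue,
    if (mode == "single_return") 1L else max_returns,
    as.numeric(ground)))

  out <- tibble::tibble(pulse_id = res$pulse_id,
                        return_index = res$return_index,
                        range_m = res$range_m,
                        is_ground = res$is_ground == 1L)
  out$ox <- origins[out$pulse_id, 1]
  out$oy <- origins[out$pulse_id, 2]
  out$oz <- origins[out$pulse_id, 3]
  out$dx <- dirs[out$pulse_id, 1]
  out$dy <- dirs[out$pulse_id, 2]
  out$dz <- dirs[out$pulse_id, 3]
  # equal split of the beam section among the recorded returns of a pulse
  out <- out |>
    dplyr::group_by(.data$pulse_id) |>
    dplyr::mutate(beam_fraction = ifelse(.data$return_index == 0, 0,
                                         1 / sum(.data$return_index > 0))) |>
    dplyr::ungroup() |>
    dplyr::select("pulse_id", "ox", "oy", "oz", "dx", "dy", "dz",
                  "return_index", "range_m", "beam_fraction", "is_ground")
  attr(out, "n_rejected") <- res$n_rejected
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  attr(out, "G") <- G
  attr(out, "max_range") <- max_range
  out
}

#' Ray traversal through a voxel grid
#'
#' Exact, gap-free voxel segments of a ray from grid entry to grid exit (or
#' `max_range`), using incremental grid stepping with half-open
#' `[entry, exit)` intervals. Segment lengths sum to the in-grid path length.
#' A ray missing the grid returns an empty tibble.
#'
#' @param origin,direction Numeric length-3; `direction` need not be unit
#'   length (it is normalised).
#' @param grid A [pad_grid()] / [attenuation_grid()] or a list with `origin`,
#'   `voxel_size` and `dims`.
#' @param max_range Maximum distance along the ray, metres.
#' @return Tibble with voxel indices `ix, iy, iz` (1-based) and `entry`,
#'   `exit` distances from the origin.
#' @export
traverse <- function(origin, direction, grid, max_range = Inf) {
  direction <- direction / sqrt(sum(direction^2))
  dims <- if (!is.null(grid$dims)) as.integer(grid$dims)
          else grid_dims(grid)
  m <- cpp_traverse(as.numeric(origin), as.numeric(direction),
                    as.numeric(grid$origin), grid$voxel_size, dims,
                    if (is.finite(max_range)) max_range else 1e12)
  tibble::as_tibble(m) |>
    dplyr::mutate(dplyr::across(c("ix", "iy", "iz"), as.integer))
}
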