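# Derived canopy products: digital terrain model from ground returns,
# height-above-ground normalisation, stratified column PAI, vertical change
# profiles and the strata boundary, and relative (percent-of-baseline) PAI.

#' Digital terrain model raster
#'
#' @param values Matrix of ground elevations (m), rows = x cells, cols = y.
#' @param origin Length-2 lower corner (x, y), metres.
#' @param resolution Cell size, metres (field default 0.5 m).
#' @return An object of class `dtm_raster`.
#' @export
dtm_raster <- function(values, origin = c(0, 0), resolution = 0.5) {
  stopifnot(is.matrix(values), resolution > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 resolution = resolution), class = "dtm_raster")
}

#' @export
print.dtm_raster <- function(x, ...) {
  cat(sprintf("<dtm_raster> %d x %d cells @ %g m, elevation %.2f-%.2f m\n",
              nrow(x$values), ncol(x$values), x$resolution,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Ground-return coordinates of a pulse set
#'
#' @param pulses Pulse tibble (see [simulate_survey()]).
#' @return Tibble with `x`, `y`, `z` of every ground return.
#' @export
ground_points <- function(pulses) {
  g <- pulses[pulses$is_ground & pulses$return_index > 0, ]
  tibble::tibble(x = g$ox + g$range_m * g$dx,
                 y = g$oy + g$range_m * g$dy,
                 z = g$oz + g$range_m * g$dz)
}

#' Build a DTM from ground returns by inverse distance weighting
#'
#' Each cell takes the IDW mean of its `k_neighbors` nearest ground points
#' (power `idw_power`); a point exactly on a cell centre is returned
#' verbatim.
#'
#' @param ground Tibble with `x`, `y`, `z` ([ground_points()] output), or a
#'   pulse tibble from which ground returns are extracted.
#' @param resolution Cell size, metres.
#' @param idw_power IDW exponent.
#' @param k_neighbors Number of nearest points per cell.
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`; defaults to the point
#'   bounding box.
#' @return A [dtm_raster()].
#' @export
build_dtm <- function(ground, resolution = 0.5, idw_power = 2,
                      k_neighbors = 10, extent = NULL) {
  if (all(c("is_ground", "range_m") %in% names(ground)))
    ground <- ground_points(ground)
  abort_if(nrow(ground) == 0, "no ground returns: cannot build a DTM")
  if (is.null(extent))
    extent <- c(min(ground$x), max(ground$x), min(ground$y), max(ground$y))
  nx <- max(1L, ceiling((extent[2] - extent[1]) / resolution))
  ny <- max(1L, ceiling((extent[4] - extent[3]) / resolution))
  cx <- extent[1] + (seq_len(nx) - 0.5) * resolution
  cy <- extent[3] + (seq_len(ny) - 0.5) * resolution
  cells <- expand.grid(x = cx, y = cy)
  z <- cpp_idw(cells$x, cells$y, ground$x, ground$y, ground$z,
               as.integer(k_neighbors), idw_power)
  dtm_raster(matrix(z, nrow = nx, ncol = ny),
             origin = c(extent[1], extent[3]), resolution = resolution)
}

# DTM elevation at arbitrary coordinates (nearest cell).
dtm_at <- function(dtm, x, y) {
  i <- pmin(pmax(floor((x - dtm$origin[1]) / dtm$resolution) + 1, 1),
            nrow(dtm$values))
  j <- pmin(pmax(floor((y - dtm$origin[2]) / dtm$resolution) + 1, 1),
            ncol(dtm$values))
  dtm$values[cbind(i, j)]
}

#' Re-reference a PAD grid to height above ground
#'
#' Shifts each vertical column down by its local ground elevation (from the
#' DTM, rounded to whole voxels so column PAD mass is conserved exactly).
#' Columns over DTM nodata are flagged unsampled.
#'
#' @param grid A [pad_grid()] with absolute heights.
#' @param dtm A [dtm_raster()] covering the grid footprint.
#' @return A [pad_grid()] with `height_reference = "above_ground"`.
#' @export
normalize_heights <- function(grid, dtm) {
  stopifnot(inherits(grid, "pad_grid"), inherits(dtm, "dtm_raster"))
  if (grid$height_reference == "above_ground") return(grid)
  d <- dim(grid$values)
  xc <- axis_centers(grid, 1); yc <- axis_centers(grid, 2)
  vals <- array(0, d)
  sampled <- if (is.null(grid$sampled)) NULL else array(FALSE, d)
  in_sampled <- grid$sampled
  flagged <- 0L
  for (i in seq_len(d[1])) {
    gz <- dtm_at(dtm, rep(xc[i], d[2]), yc)
    for (j in seq_len(d[2])) {
      if (is.na(gz[j])) { flagged <- flagged + 1L
        if (!is.null(sampled)) sampled[i, j, ] <- FALSE
        vals[i, j, ] <- NA_real_
        next
      }
      shift <- as.integer(round((gz[j] - grid$origin[3]) / grid$voxel_size))
      src <- seq_len(d[3])
      dst <- src - shift
      ok <- dst >= 1 & dst <= d[3]
      vals[i, j, dst[ok]] <- grid$values[i, j, src[ok]]
      if (!is.null(sampled)) sampled[i, j, dst[ok]] <- in_sampled[i, j, src[ok]]
    }
  }
  pad_grid(vals, origin = c(grid$origin[1], grid$origin[2], 0),
           voxel_size = grid$voxel_size, height_reference = "above_ground",
           sampled = sampled,
           provenance = c(grid$provenance,
                          list(height_normalized = TRUE,
                               columns_flagged = flagged)))
}

#' Column plant area index by stratum
#'
#' PAI of a 1 m^2 vertical column is the sum of its voxel PADs times the
#' voxel height; the understory stratum collects voxels whose centre lies
#' below the strata boundary (default 15 m above ground) and the upper canopy
#' the rest, so `total = understory + upper_canopy` exactly. Unsampled voxels
#' are excluded from the sums and reported through the per-column sampled
#' fraction; columns below `min_sampled_frac` are omitted (count reported via
#' `attr(, "n_omitted")`).
#'
#' @param grid A [pad_grid()] with heights above ground.
#' @param strata_boundary Height splitting the strata, metres above ground.
#' @param min_sampled_frac Minimum fraction of a column's voxels sampled for
#'   the column to be kept.
#' @return Tibble with `column_x`, `column_y`, `stratum` (`understory`,
#'   `upper_canopy`, `total`), `pai`, `sampled_frac`.
#' @export
column_pai <- function(grid, strata_boundary = 15, min_sampled_frac = 0.8) {
  stopifnot(inherits(grid, "pad_grid"))
  if (grid$height_reference != "above_ground")
    warning("grid heights are not referenced above ground; ",
            "strata split uses absolute z", call. = FALSE)
  d <- dim(grid$values)
  zc <- axis_centers(grid, 3)
  under <- zc < strata_boundary
  sampled <- grid$sampled %||% array(TRUE, d)
  vals <- grid$values
  vals[!sampled | is.na(vals)] <- 0

  sum_stratum <- function(sel) {
    apply(vals[, , sel, drop = FALSE], c(1, 2), sum) * grid$voxel_size
  }
  pai_u <- sum_stratum(under)
  pai_c <- sum_stratum(!under)
  sfrac <- apply(sampled, c(1, 2), mean)

  xc <- axis_centers(grid, 1); yc <- axis_centers(grid, 2)
  base <- tibble::tibble(
    column_x = rep(xc, times = d[2]),
    column_y = rep(yc, each = d[1]),
    understory = as.vector(pai_u),
    upper_canopy = as.vector(pai_c),
    sampled_frac = as.vector(sfrac)
  )
  keep <- base$sampled_frac >= min_sampled_frac
  n_omitted <- sum(!keep)
  if (n_omitted > 0)
    message(n_omitted, " column(s) below the sampled-fraction threshold omitted")
  out <- base[keep, ] |>
    dplyr::mutate(total = .data$understory + .data$upper_canopy) |>
    tidyr::pivot_longer(c("understory", "upper_canopy", "total"),
                        names_to = "stratum", values_to = "pai") |>
    dplyr::select("column_x", "column_y", "stratum", "pai", "sampled_frac")
  attr(out, "n_omitted") <- n_omitted
  attr(out, "strata_boundary") <- strata_boundary
  out
}

#' Assemble PAI panel rows from column PAI
#'
#' Adds the survey/transect/edge metadata that the edge and phenology models
#' expect, treating `column_x` as distance to the forest edge unless a
#' distance is supplied.
#'
#' @param columns [column_pai()] output.
#' @param survey_time Survey label (date or index).
#' @param transect_id Transect identifier.
#' @param distance_to_edge Optional vector overriding `column_x`.
#' @param edge_threshold Edge/interior split distance, metres.
#' @return A PAI panel tibble with columns `column_x`, `column_y`,
#'   `transect_id`, `distance_to_edge`, `edge_class`, `survey_time`,
#'   `stratum`, `pai`.
#' @export
as_pai_panel <- function(columns, survey_time, transect_id = "T1",
                         distance_to_edge = NULL, edge_threshold = 40) {
  columns |>
    dplyr::mutate(
      transect_id = transect_id,
      distance_to_edge = distance_to_edge %||% .data$column_x,
      edge_class = classify_edge(.data$distance_to_edge, edge_threshold),
      survey_time = survey_time
    ) |>
    dplyr::select("column_x", "column_y", "transect_id", "distance_to_edge",
                  "edge_class", "survey_time", "stratum", "pai",
                  dplyr::any_of("sampled_frac"))
}

#' Vertical PAD change profile between two surveys
#'
#' Mean over columns, per 1-voxel height bin, of `grid_b - grid_a` (the later
#' survey minus the earlier). Only voxels sampled in both grids contribute.
#'
#' @param grid_a,grid_b [pad_grid()]s sharing geometry; `grid_b` is the later
#'   survey.
#' @param labels Length-2 labels for the reference and comparison surveys.
#' @return Tibble of class `change_profile` with `height` (bin centre, m) and
#'   `delta_pad` (m^2 m^-3).
#' @export
pad_change_profile <- function(grid_a, grid_b,
                               labels = c("reference", "comparison")) {
  stopifnot(inherits(grid_a, "pad_grid"), inherits(grid_b, "pad_grid"))
  abort_if(!identical(dim(grid_a$values), dim(grid_b$values)) ||
             any(abs(grid_a$origin - grid_b$origin) > 1e-9) ||
             abs(grid_a$voxel_size - grid_b$voxel_size) > 1e-9,
           "grids do not share geometry")
  d <- dim(grid_a$values)
  ok <- (grid_a$sampled %||% array(TRUE, d)) & (grid_b$sampled %||% array(TRUE, d))
  delta <- grid_b$values - grid_a$values
  delta[!ok] <- NA_real_
  prof <- apply(delta, 3, mean, na.rm = TRUE)
  out <- tibble::tibble(height = axis_centers(grid_a, 3), delta_pad = prof)
  class(out) <- c("change_profile", class(out))
  attr(out, "labels") <- labels
  out
}

#' Detect the strata boundary from a PAD change profile
#'
#' Smooths the profile with a centred moving average and looks for the
#' height at which the mean PAD change flips from positive (below: understory
#' gain) to negative (above: upper canopy loss). With several candidate
#' crossings, the one maximising sign consistency (fraction of bins positive
#' below and negative above) is returned, together with the crossing count.
#' A profile with no sign change (or all zero) yields a no-boundary result,
#' distinct from a boundary at 0 m.
#'
#' @param profile A [pad_change_profile()] result (or tibble with `height`,
#'   `delta_pad`).
#' @param smooth_window Moving-average window in bins (odd).
#' @return List of class `strata_boundary`: `boundary` (m, `NA` if none),
#'   `n_crossings`, `sign_consistency`, `reason`.
#' @export
detect_strata_boundary <- function(profile, smooth_window = 3) {
  h <- profile$height
  y <- profile$delta_pad
  keep <- !is.na(y)
  h <- h[keep]; y <- y[keep]
  res <- function(boundary, ncross, cons, reason = NA_character_)
    structure(list(boundary = boundary, n_crossings = ncross,
                   sign_consistency = cons, reason = reason),
              class = "strata_boundary")
  if (length(y) < 3 || all(y == 0))
    return(res(NA_real_, 0L, NA_real_, "profile flat or empty"))
  k <- max(1L, as.integer(smooth_window))
  s <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- y[is.na(s)]
  cross <- which(s[-length(s)] > 0 & s[-1] <= 0)
  if (length(cross) == 0)
    return(res(NA_real_, 0L, NA_real_, "no positive-to-negative crossing"))
  consistency <- vapply(cross, function(i) {
    (sum(s[seq_len(i)] > 0) + sum(s[-seq_len(i)] < 0)) / length(s)
  }, numeric(1))
  best <- cross[which.max(consistency)]
  # linear interpolation of the zero crossing between bin centres
  b <- if (s[best + 1] == s[best]) mean(h[best + 0:1]) else
    h[best] + (h[best + 1] - h[best]) * s[best] / (s[best] - s[best + 1])
  res(b, length(cross), max(consistency))
}

#' @export
print.strata_boundary <- function(x, ...) {
  if (is.na(x$boundary))
    cat("<strata_boundary> none detected:", x$reason, "\n")
  else
    cat(sprintf("<strata_boundary> %.2f m (crossings: %d, sign consistency %.2f)\n",
                x$boundary, x$n_crossings, x$sign_consistency))
  invisible(x)
}

#' Relative PAI (percent of a baseline survey)
#'
#' Divides each column x stratum PAI trajectory by its value at the baseline
#' survey, times 100; baseline rows are exactly 100. Columns with a zero
#' baseline are excluded (count in `attr(, "n_zero_baseline")`).
#'
#' @param panel PAI panel tibble (see [as_pai_panel()]).
#' @param baseline_time The `survey_time` value used as 100%.
#' @return The panel with a `pai_rel` column (percent).
#' @export
relative_pai <- function(panel, baseline_time) {
  abort_if(!baseline_time %in% panel$survey_time,
           "baseline_time not present in panel")
  out <- panel |>
    dplyr::group_by(.data$column_x, .data$column_y, .data$transect_id,
                    .data$stratum) |>
    dplyr::mutate(.base = .data$pai[match(baseline_time, .data$survey_time)]) |>
    dplyr::ungroup()
  abort_if(any(is.na(out$.base)),
           "baseline survey missing for some column/stratum groups")
  nzero <- sum(out$.base == 0 & out$survey_time == baseline_time)
  if (nzero > 0)
    message(nzero, " column/stratum group(s) with zero baseline excluded")
  out <- out |>
    dplyr::filter(.data$.base > 0) |>
    dplyr::mutate(pai_rel = 100 * .data$pai / .data$.base) |>
    dplyr::select(-".base")
  attr(out, "n_zero_baseline") <- nzero
  attr(out, "baseline_time") <- baseline_time
  out
}
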