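# Voxel-grid containers. A pad_grid is a 3-D array of plant area density
# (m^2 m^-3) on a cubic voxel lattice, with an origin, a voxel size and a
# height reference ("absolute" z or "above_ground"). Attenuation grids share
# the geometry and carry the directional attenuation coefficient lambda
# (m^-1) plus per-voxel sampled flags.

#' Plant area density grid
#'
#' @param values 3-D numeric array of PAD (m^2 m^-3), indexed x, y, z.
#' @param origin Numeric length-3, metres: lower corner of voxel (1,1,1).
#' @param voxel_size Voxel edge length, metres.
#' @param height_reference `"absolute"` (z is elevation) or `"above_ground"`.
#' @param sampled Optional logical array of the same dimension marking voxels
#'   with any pulse coverage; `NULL` means fully sampled.
#' @param provenance Named list of free-form metadata (estimator, cap, pulse
#'   count, ...).
#' @return An object of class `pad_grid`.
#' @export
pad_grid <- function(values, origin = c(0, 0, 0), voxel_size = 1,
                     height_reference = c("absolute", "above_ground"),
                     sampled = NULL, provenance = list()) {
  height_reference <- match.arg(height_reference)
  stopifnot(is.array(values), length(dim(values)) == 3,
            length(origin) == 3, voxel_size > 0)
  abort_if(any(!is.finite(values) & !is.na(values)),
           "PAD values must be finite or NA")
  abort_if(any(values < 0, na.rm = TRUE), "PAD values must be >= 0")
  if (!is.null(sampled)) stopifnot(identical(dim(sampled), dim(values)))
  structure(list(values = values, origin = as.numeric(origin),
                 voxel_size = voxel_size,
                 height_reference = height_reference,
                 sampled = sampled, provenance = provenance),
            class = "pad_grid")
}

#' @export
print.pad_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pad_grid> %d x %d x %d voxels (%.2g m), origin (%g, %g, %g), heights %s\n",
              d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2],
              x$origin[3], x$height_reference))
  sf <- if (is.null(x$sampled)) 1 else mean(x$sampled)
  cat(sprintf("  PAD mean %.3f m2/m3 (sampled fraction %.2f)\n",
              mean(x$values[if (is.null(x$sampled)) TRUE else x$sampled],
                   na.rm = TRUE), sf))
  invisible(x)
}

#' Attenuation-coefficient grid
#'
#' @param lambda 3-D array of directional attenuation coefficients (m^-1).
#' @param sampled Logical array: voxels entered by at least one beam fraction.
#' @param G Projection-function constant used downstream (0.5 for a spherical
#'   leaf-angle distribution).
#' @param cap_lambda Cap applied where the path denominator vanishes (m^-1).
#' @inheritParams pad_grid
#' @return An object of class `attenuation_grid`.
#' @export
attenuation_grid <- function(lambda, sampled, origin = c(0, 0, 0),
                             voxel_size = 1,
                             height_reference = c("absolute", "above_ground"),
                             G = 0.5, cap_lambda = 8, provenance = list()) {
  height_reference <- match.arg(height_reference)
  stopifnot(is.array(lambda), identical(dim(lambda), dim(sampled)))
  abort_if(any(lambda[sampled] < 0, na.rm = TRUE), "lambda must be >= 0")
  structure(list(lambda = lambda, sampled = sampled,
                 origin = as.numeric(origin), voxel_size = voxel_size,
                 height_reference = height_reference, G = G,
                 cap_lambda = cap_lambda, provenance = provenance),
            class = "attenuation_grid")
}

#' @export
print.attenuation_grid <- function(x, ...) {
  d <- dim(x$lambda)
  cat(sprintf("<attenuation_grid> %d x %d x %d voxels, G = %g, cap = %g m^-1\n",
              d[1], d[2], d[3], x$G, x$cap_lambda))
  cat(sprintf("  sampled %.1f%%, mean lambda %.3f m^-1\n",
              100 * mean(x$sampled), mean(x$lambda[x$sampled])))
  invisible(x)
}

grid_dims <- function(grid) dim(grid$values %||% grid$lambda)

# Voxel centre coordinates along one axis.
axis_centers <- function(grid, axis) {
  d <- grid_dims(grid)[axis]
  grid$origin[axis] + (seq_len(d) - 0.5) * grid$voxel_size
}

#' Convert a grid to a long tibble
#'
#' One row per voxel with centre coordinates, the stored value and the sampled
#' flag, suitable for dplyr/ggplot2 work and for the long-format CSV on disk.
#'
#' @param grid A [pad_grid()] or [attenuation_grid()].
#' @return A tibble with columns `x`, `y`, `z`, `value`, `sampled`.
#' @export
grid_to_tibble <- function(grid) {
  vals <- grid$values %||% grid$lambda
  d <- dim(vals)
  sampled <- grid$sampled %||% array(TRUE, d)
  tibble::tibble(
    x = rep(axis_centers(grid, 1), times = d[2] * d[3]),
    y = rep(rep(axis_centers(grid, 2), each = d[1]), times = d[3]),
    z = rep(axis_centers(grid, 3), each = d[1] * d[2]),
    value = as.vector(vals),
    sampled = as.vector(sampled)
  )
}
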