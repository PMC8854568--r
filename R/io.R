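# Plain-text interchange formats: the pulse CSV dialect (one row per return,
# marker rows with return_index 0 for no-return pulses), long-format grid
# CSV with a geometry header line, panels and climate series as ISO-8601
# CSV, fits as JSON and run configs as YAML.

#' Write / read pulse records as CSV
#'
#' Columns: `pulse_id, ox, oy, oz, dx, dy, dz, return_index, range_m,
#' beam_fraction, is_ground`. A pulse with no returns appears once with
#' `return_index = 0` and an empty range so that its survivor path is kept.
#'
#' @param pulses Pulse tibble (see [simulate_survey()]).
#' @param path File path.
#' @return `write_pulses()` returns `path` invisibly; `read_pulses()` the
#'   pulse tibble.
#' @export
write_pulses <- function(pulses, path) {
  readr::write_csv(pulses, path)
  invisible(path)
}

#' @rdname write_pulses
#' @export
read_pulses <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    pulse_id = readr::col_integer(), ox = "d", oy = "d", oz = "d",
    dx = "d", dy = "d", dz = "d", return_index = readr::col_integer(),
    range_m = "d", beam_fraction = "d",
    is_ground = readr::col_logical()))
}

#' Write / read a voxel grid as long-format CSV
#'
#' One row per voxel (`x, y, z` centres, `value`, `sampled`) preceded by a
#' `#` header line carrying the geometry (origin, voxel size, dims, height
#' reference) so the array reconstructs exactly.
#'
#' @param grid A [pad_grid()] or [attenuation_grid()].
#' @param path File path.
#' @export
write_grid_csv <- function(grid, path) {
  d <- grid_dims(grid)
  kind <- if (inherits(grid, "pad_grid")) "pad" else "lambda"
  header <- sprintf(
    "# canopyphen_grid kind=%s origin=%g,%g,%g voxel_size=%g dims=%d,%d,%d height_reference=%s",
    kind, grid$origin[1], grid$origin[2], grid$origin[3], grid$voxel_size,
    d[1], d[2], d[3], grid$height_reference)
  writeLines(header, path)
  suppressWarnings(readr::write_csv(grid_to_tibble(grid), path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  header <- readLines(path, n = 1)
  abort_if(!grepl("^# canopyphen_grid", header), "not a canopyphen grid CSV")
  get_field <- function(name) sub(sprintf(".*%s=([^ ]+).*", name), "\\1", header)
  origin <- as.numeric(strsplit(get_field("origin"), ",")[[1]])
  vs <- as.numeric(get_field("voxel_size"))
  dims <- as.integer(strsplit(get_field("dims"), ",")[[1]])
  href <- get_field("height_reference")
  kind <- get_field("kind")
  tb <- readr::read_csv(path, comment = "#", col_types = "ddddl")
  vals <- array(tb$value, dims)
  sampled <- array(tb$sampled, dims)
  if (kind == "pad")
    pad_grid(vals, origin, vs, href, sampled = sampled)
  else
    attenuation_grid(vals, sampled, origin, vs, href)
}

#' Write / read a PAI panel (or any tibble with dates) as CSV
#'
#' @param panel Tibble.
#' @param path File path.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("time" %in% names(out)) out$time <- factor(out$time)
  out
}

#' Serialize a fitted model summary to JSON
#'
#' Writes the tidy coefficients, glance row and any variance components of a
#' fitted object (edge, hockey, phenology, coupling) as pretty JSON.
#'
#' @param fit A fitted object from this package.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(class = class(fit)[1],
                  coefficients = tryCatch(tidy(fit), error = function(e) NULL),
                  summary = tryCatch(glance(fit), error = function(e) NULL))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Write / read a run configuration as YAML
#'
#' Configurations round-trip losslessly (dates serialised as ISO strings).
#'
#' @param config A [run_config()] list.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(serialize_dates(unclass(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- restore_dates(yaml::read_yaml(path))
  class(cfg) <- "run_config"
  cfg
}

serialize_dates <- function(x) {
  if (inherits(x, "Date")) return(paste0("DATE:", format(x, "%Y-%m-%d")))
  if (is.list(x)) return(lapply(x, serialize_dates))
  x
}

restore_dates <- function(x) {
  if (is.character(x) && all(grepl("^DATE:", x)))
    return(as.Date(sub("^DATE:", "", x)))
  if (is.list(x)) return(lapply(x, restore_dates))
  x
}
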