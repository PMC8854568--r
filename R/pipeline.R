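# End-to-end orchestration: simulate -> voxelize -> metrics -> edge ->
# phenology -> climate, with a single config, per-stage seeds derived from
# one master seed, CSV/JSON artifacts and a run manifest (inputs, outputs,
# checksums, versions, wall clock). Re-running an identical config
# reproduces stochastic outputs bit-identically.

#' Pipeline run configuration
#'
#' @param output_dir Directory for artifacts (created if missing).
#' @param seed Master seed; each stage derives its own stream from it.
#' @param stages Character vector of stages to run, in dependency order, a
#'   subset of `c("simulate", "voxelize", "metrics", "edge", "phenology",
#'   "climate")`.
#' @param scene A [scene_config()]; its extent/seasonal table drive the
#'   simulation.
#' @param surveys Survey indices to simulate/voxelize.
#' @param angular_resolution Scanner angular step (mdeg) used for the
#'   simulated surveys.
#' @param mode Survey simulation mode.
#' @param estimator,cap_lambda,G Attenuation estimation settings.
#' @param strata_boundary Strata split height, m above ground.
#' @param edge_threshold Edge class threshold, m.
#' @param perms Permutation-envelope resamples for the phenology stage.
#' @param panel_from `"voxels"` (build the panel from the voxelized grids)
#'   or `"direct"` (use [simulate_pai_panel()], faster).
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("canopyphen_run_"), seed = 1L,
                       stages = c("simulate", "voxelize", "metrics", "edge",
                                  "phenology", "climate"),
                       scene = scene_config(extent = c(30, 10, 35)),
                       surveys = c(1L, 11L), angular_resolution = 2000,
                       mode = "multi_return",
                       estimator = "fpl_mle", cap_lambda = 8, G = 0.5,
                       strata_boundary = 15, edge_threshold = 40,
                       perms = 200, panel_from = "direct") {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 stages = stages, scene = scene, surveys = surveys,
                 angular_resolution = angular_resolution, mode = mode,
                 estimator = estimator, cap_lambda = cap_lambda, G = G,
                 strata_boundary = strata_boundary,
                 edge_threshold = edge_threshold, perms = perms,
                 panel_from = panel_from),
            class = "run_config")
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order, writing artifacts and
#' a manifest to the configured output directory. A downstream stage whose
#' upstream artifact is missing (neither produced in this run nor cached
#' from a previous one) fails with an error naming the stage to run first.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return The manifest (list), invisibly also written as `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- function(...) file.path(config$output_dir, paste0(...))
  files <- character()
  need <- function(path, producer) {
    abort_if(!file.exists(path),
             sprintf("missing upstream artifact %s: run stage '%s' first",
                     basename(path), producer))
    path
  }

  if ("simulate" %in% config$stages) {
    for (s in config$surveys) {
      say("simulate: survey ", s)
      truth <- build_truth_grid(config$scene, s)
      layout <- scanner_layout(
        footprint = config$scene$extent[1:2],
        angular_resolution = config$angular_resolution)
      pulses <- simulate_survey(truth, layout, mode = config$mode,
                                seed = derive_seed(config$seed,
                                                   paste0("survey", s)),
                                G = config$G, ground = config$scene$ground)
      files <- c(files, write_pulses(pulses, out("pulses_s", s, ".csv")),
                 write_grid_csv(truth, out("truth_s", s, ".csv")))
    }
    rain <- simulate_rainfall(seed = derive_seed(config$seed, "rain"))
    micro <- simulate_microclimate(
      microclimate_config(n_edge = 4, n_interior = 4),
      seed = derive_seed(config$seed, "micro"))
    files <- c(files, write_panel(rain, out("rainfall.csv")),
               write_panel(micro, out("microclimate.csv")))
  }

  if ("voxelize" %in% config$stages) {
    for (s in config$surveys) {
      say("voxelize: survey ", s)
      pulses <- read_pulses(need(out("pulses_s", s, ".csv"), "simulate"))
      geom <- list(origin = c(0, 0, 0), voxel_size = config$scene$voxel_size,
                   dims = as.integer(round(config$scene$extent /
                                             config$scene$voxel_size)))
      acc <- accumulate(pulses, geom)
      att <- estimate_lambda(acc, config$estimator, config$cap_lambda,
                             config$G)
      pad <- pad_from_lambda(att)
      files <- c(files, write_grid_csv(pad, out("pad_s", s, ".csv")))
    }
  }

  if ("metrics" %in% config$stages) {
    say("metrics")
    s1 <- config$surveys[1]
    pulses <- read_pulses(need(out("pulses_s", s1, ".csv"), "simulate"))
    dtm <- build_dtm(pulses, resolution = 0.5)
    grids <- lapply(config$surveys, function(s) {
      g <- read_grid_csv(need(out("pad_s", s, ".csv"), "voxelize"))
      normalize_heights(g, dtm)
    })
    dates <- config$scene$seasonal_multipliers |>
      dplyr::distinct(.data$survey, .data$date)
    panel <- purrr::map2_dfr(grids, config$surveys, function(g, s) {
      as_pai_panel(column_pai(g, config$strata_boundary),
                   survey_time = dates$date[match(s, dates$survey)],
                   transect_id = "T1",
                   edge_threshold = config$edge_threshold)
    })
    files <- c(files, write_panel(panel, out("pai_panel_voxel.csv")))
    if (length(grids) >= 2) {
      prof <- pad_change_profile(grids[[1]], grids[[length(grids)]])
      sb <- detect_strata_boundary(prof)
      files <- c(files, write_panel(prof, out("change_profile.csv")))
      jsonlite::write_json(list(boundary = sb$boundary,
                                n_crossings = sb$n_crossings),
                           out("strata_boundary.json"), auto_unbox = TRUE,
                           digits = NA)
      files <- c(files, out("strata_boundary.json"))
    }
  }

  panel <- NULL
  panel_path <- out("pai_panel.csv")
  if (any(c("edge", "phenology") %in% config$stages)) {
    if (config$panel_from == "direct") {
      panel <- simulate_pai_panel(panel_design(),
                                  seed = derive_seed(config$seed, "panel"))
      files <- c(files, write_panel(panel, panel_path))
    } else {
      panel <- read_panel(need(out("pai_panel_voxel.csv"), "metrics"))
    }
  }

  if ("edge" %in% config$stages) {
    say("edge models")
    tot <- panel[panel$stratum == "total", ]
    efit <- fit_edge_model(tot)
    hfit <- fit_hockey_stick(tot)
    files <- c(files, write_fit_json(efit, out("edge_model.json")),
               write_fit_json(hfit, out("hockey.json")))
  }

  if ("phenology" %in% config$stages) {
    say("phenology models")
    for (st in c("understory", "upper_canopy", "total")) {
      fits <- lapply(
        c(interaction = "interaction", additive = "additive",
          edge_plus_interaction = "edge_plus_interaction"),
        function(m) fit_phenology_lme(panel, st, m))
      sel <- select_model(fits)
      env <- permutation_ci(panel, st, model = sel$best_name,
                            n = config$perms,
                            seed = derive_seed(config$seed,
                                               paste0("perm", st)))
      readr::write_csv(env$cell_envelope,
                       out("phenology_cells_", st, ".csv"))
      files <- c(files, write_fit_json(sel$best,
                                       out("phenology_", st, ".json")),
                 out("phenology_cells_", st, ".csv"))
    }
  }

  if ("climate" %in% config$stages) {
    say("climate")
    rain <- read_panel(need(out("rainfall.csv"), "simulate"))
    rain$date <- as.Date(rain$date)
    seasons <- classify_dry_season(running_rainfall(rain))
    micro <- read_panel(need(out("microclimate.csv"), "simulate"))
    daily <- daily_aggregate(micro)
    files <- c(files,
               write_panel(seasons$series, out("season_labels.csv")),
               write_panel(daily, out("microclimate_daily.csv")))
  }

  files <- unique(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("canopyphen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, stages = config$stages,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(config, file.path(config$output_dir, "run_config.yaml"))
  invisible(manifest)
}
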