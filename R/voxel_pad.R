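# Voxel attenuation and PAD estimation from pulse records. The estimator
# follows the free-path model: within a voxel, interception distance is
# exponential with rate lambda, censored at the voxel exit (or at a terminal
# ground return). Each beam fraction w entering a voxel contributes w to the
# entering weight; an intercepted fraction contributes its weight and its
# free path (entry to hit); surviving fractions contribute weight x potential
# path. The weighted censored-exponential MLE is then
# lambda_hat = intercepted / (free path + survivor path).

#' Accumulate per-voxel attenuation statistics from pulse records
#'
#' Walks every pulse through the grid geometry and deposits beam-fraction
#' weighted sufficient statistics per voxel. For a pulse with k recorded
#' returns each return carries fraction 1/k of the beam section (the
#' equal-split rule); the weight entering a voxel is 1 minus the fractions
#' already deposited at earlier hits. Ground returns terminate the pulse and
#' are excluded from vegetation interception (the surviving fraction's path
#' is censored at the ground hit); no-return pulses contribute survivor path
#' along their whole in-grid path.
#'
#' @param pulses Pulse tibble as produced by [simulate_survey()] or
#'   [read_pulses()].
#' @param grid Grid geometry: a [pad_grid()], [attenuation_grid()], or list
#'   with `origin`, `voxel_size`, `dims`.
#' @param max_range Maximum tracked range, metres.
#' @param exclude_ground Keep ground returns out of vegetation interception
#'   (default, matching the estimator's assumptions).
#' @return An object of class `voxel_accumulator`: arrays `entering_weight`,
#'   `intercepted_weight`, `weighted_free_path`, `weighted_survivor_path`,
#'   `weighted_potential_path` (weight times full segment length, used by the
#'   Beer--Lambert cross-check), `ray_count`, plus geometry and a count of
#'   returns that fell outside the traversed extent (`skipped_returns`,
#'   logged not erred).
#' @export
accumulate <- function(pulses, grid, max_range = attr(pulses, "max_range") %||% 350,
                       exclude_ground = TRUE) {
  needed <- c("pulse_id", "ox", "oy", "oz", "dx", "dy", "dz",
              "return_index", "range_m", "beam_fraction", "is_ground")
  abort_if(!all(needed %in% names(pulses)), "pulses is missing required columns")
  dims <- if (!is.null(grid$dims)) as.integer(grid$dims) else grid_dims(grid)

  p <- dplyr::arrange(pulses, .data$pulse_id, .data$return_index)
  rets <- p[p$return_index > 0, ]
  abort_if(any(rets$beam_fraction <= 0 | rets$beam_fraction > 1),
           "beam fractions must lie in (0, 1]")
  first <- !duplicated(p$pulse_id)
  ids <- p$pulse_id[first]
  origins <- as.matrix(p[first, c("ox", "oy", "oz")])
  dirs <- as.matrix(p[first, c("dx", "dy", "dz")])
  nret <- tabulate(match(rets$pulse_id, ids), nbins = length(ids))
  offsets <- c(0L, cumsum(nret))

  res <- cpp_accumulate(origins, dirs, offsets, rets$range_m,
                        rets$beam_fraction, as.integer(rets$is_ground),
                        as.numeric(grid$origin), grid$voxel_size, dims,
                        max_range, exclude_ground)
  out <- list(
    entering_weight = array(res$entering_weight, dims),
    intercepted_weight = array(res$intercepted_weight, dims),
    weighted_free_path = array(res$weighted_free_path, dims),
    weighted_survivor_path = array(res$weighted_survivor_path, dims),
    weighted_potential_path = array(res$weighted_potential_path, dims),
    ray_count = array(res$ray_count, dims),
    origin = as.numeric(grid$origin), voxel_size = grid$voxel_size,
    dims = dims, n_pulses = length(ids),
    skipped_returns = res$skipped_returns
  )
  class(out) <- "voxel_accumulator"
  out
}

#' @export
print.voxel_accumulator <- function(x, ...) {
  cat(sprintf("<voxel_accumulator> %s voxels, %d pulses, %d skipped returns\n",
              paste(x$dims, collapse = " x "), x$n_pulses, x$skipped_returns))
  cat(sprintf("  sampled voxels: %d (%.1f%%)\n", sum(x$entering_weight > 0),
              100 * mean(x$entering_weight > 0)))
  invisible(x)
}

#' Estimate the attenuation coefficient per voxel
#'
#' `fpl_mle` (default) is the closed-form maximiser of the weighted
#' censored-exponential log-likelihood
#' `sum_hits w (log(lambda) - lambda z) - sum_surv w lambda l`:
#' `lambda_hat = intercepted_weight / (weighted_free_path +
#' weighted_survivor_path)`. `beer_lambert` is the cross-check ratio
#' estimator `-log(surviving / entering) / mean weighted potential path`.
#' Voxels never
#' entered are flagged unsampled (never silently zero-filled); voxels with
#' interceptions but vanishing path are capped at `cap_lambda`.
#'
#' @param acc A [accumulate()] result.
#' @param estimator `"fpl_mle"` or `"beer_lambert"`.
#' @param cap_lambda Cap for fully occluding voxels, m^-1.
#' @param G Projection constant stored on the result for PAD conversion.
#' @param min_rays Minimum pulses through a voxel for it to count as
#'   sampled (default 1, i.e. any entering beam fraction). Raising it flags
#'   grazed voxels whose handful of short path fragments produce unstable,
#'   often capped estimates that would otherwise distort column sums.
#' @return An [attenuation_grid()].
#' @export
estimate_lambda <- function(acc, estimator = c("fpl_mle", "beer_lambert"),
                            cap_lambda = 8, G = 0.5, min_rays = 1) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(acc, "voxel_accumulator"))
  ew <- acc$entering_weight; iw <- acc$intercepted_weight
  fp <- acc$weighted_free_path; sp <- acc$weighted_survivor_path
  abort_if(any(ew < 0) || any(iw < 0) || any(fp < 0) || any(sp < 0),
           "corrupted accumulator: negative sufficient statistics")
  abort_if(any(iw > ew + 1e-9), "corrupted accumulator: intercepted > entering")
  sampled <- ew > 0 & acc$ray_count >= min_rays
  path <- fp + sp
  if (estimator == "fpl_mle") {
    lam <- ifelse(iw == 0, 0, ifelse(path > 0, iw / path, cap_lambda))
  } else {
    surv <- pmax(ew - iw, 0)
    # mean potential (uncensored) path per unit entering weight
    mean_path <- ifelse(ew > 0, acc$weighted_potential_path / ew, 0)
    lam <- ifelse(iw == 0, 0,
                  ifelse(surv > 0 & mean_path > 0,
                         -log(surv / ew) / mean_path, cap_lambda))
  }
  lam <- pmin(lam, cap_lambda)
  lam[!sampled] <- NA_real_
  attenuation_grid(array(lam, acc$dims), array(sampled, acc$dims),
                   origin = acc$origin, voxel_size = acc$voxel_size,
                   G = G, cap_lambda = cap_lambda,
                   provenance = list(estimator = estimator,
                                     cap_lambda = cap_lambda,
                                     n_pulses = acc$n_pulses))
}

#' Convert attenuation to plant area density
#'
#' PAD = lambda / G per sampled voxel, with G the projection function (0.5
#' under a spherical leaf-angle distribution). Unsampled flags propagate.
#'
#' @param att An [attenuation_grid()].
#' @param G Projection constant; defaults to the one stored on `att`.
#' @return A [pad_grid()] with provenance carried over.
#' @export
pad_from_lambda <- function(att, G = att$G) {
  stopifnot(inherits(att, "attenuation_grid"))
  abort_if(!is.numeric(G) || G <= 0, "G must be > 0")
  vals <- att$lambda / G
  pad_grid(vals, origin = att$origin, voxel_size = att$voxel_size,
           height_reference = att$height_reference, sampled = att$sampled,
           provenance = c(att$provenance, list(G = G)))
}
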