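# Shared fixture builders; all fixtures are generated in code.

# homogeneous PAD grid
homo_grid <- function(pad = 0.5, dims = c(10, 10, 10), voxel = 1) {
  pad_grid(array(pad, dims), voxel_size = voxel)
}

# random pulse bundle through a grid: origins uniform in the volume,
# isotropic directions (a sampling-design-free harness for estimator tests)
random_bundle <- function(grid, n, seed = 1) {
  d <- dim(grid$values) * grid$voxel_size
  with_seed(seed, list(
    origins = cbind(runif(n, 0, d[1]), runif(n, 0, d[2]), runif(n, 0, d[3])),
    dirs = {
      z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
      r <- sqrt(pmax(0, 1 - z^2))
      cbind(r * cos(phi), r * sin(phi), z)
    },
    max_range = 400, max_returns = 8L))
}

# minimal hand-built pulse tibble
pulse_row <- function(pulse_id, o, d, returns = NULL) {
  d <- d / sqrt(sum(d^2))
  if (is.null(returns))
    return(tibble::tibble(pulse_id = pulse_id, ox = o[1], oy = o[2],
                          oz = o[3], dx = d[1], dy = d[2], dz = d[3],
                          return_index = 0L, range_m = NA_real_,
                          beam_fraction = 0, is_ground = FALSE))
  tibble::tibble(pulse_id = pulse_id, ox = o[1], oy = o[2], oz = o[3],
                 dx = d[1], dy = d[2], dz = d[3],
                 return_index = seq_len(nrow(returns)),
                 range_m = returns$range, beam_fraction = returns$fraction,
                 is_ground = returns$is_ground)
}

# small noise-free panel design shortcuts
quiet_design <- function(...) {
  panel_design(sd_transect = 0, sd_edge_within = 0, sd_resid = 0, ...)
}
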