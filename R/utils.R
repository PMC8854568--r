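# Small shared helpers and the analytic scanner-geometry / G-function results.

#' Angular point spacing of a scan pattern
#'
#' Arc-length spacing between neighbouring beams of a scanner with a given
#' angular step, at a given range: `range * step` (step in radians). A 40 mdeg
#' step gives 1.4 cm spacing at 20 m and about 35 mm at 50 m.
#'
#' @param range_m Range from the scanner, metres.
#' @param angular_resolution_mdeg Angular step in milli-degrees (1 mdeg =
#'   0.001 degree).
#' @return Point spacing in metres.
#' @examples
#' point_spacing(20, 40) * 100 # cm
#' @export
point_spacing <- function(range_m, angular_resolution_mdeg = 40) {
  stopifnot(all(range_m >= 0), all(angular_resolution_mdeg > 0))
  range_m * angular_resolution_mdeg / 1000 * pi / 180
}

#' Projection function G for a spherical leaf-angle distribution
#'
#' The G-function is the ratio of leaf area projected along the beam direction
#' to actual one-sided leaf area. For leaf normals distributed uniformly over
#' the sphere it equals `E|cos(angle)| = 1/2` for any beam direction; the
#' closed form is returned by default, and `method = "monte_carlo"` checks it
#' by averaging `|cos|` over random unit normals.
#'
#' @param method `"closed_form"` or `"monte_carlo"`.
#' @param n Number of Monte-Carlo normals.
#' @param beam Beam direction (any non-zero 3-vector); irrelevant for the
#'   closed form by symmetry.
#' @param seed Optional RNG seed for the Monte-Carlo route.
#' @return The scalar G value.
#' @export
g_spherical <- function(method = c("closed_form", "monte_carlo"), n = 1e6,
                        beam = c(0, 0, 1), seed = NULL) {
  method <- match.arg(method)
  if (method == "closed_form") return(0.5)
  with_seed(seed, {
    # isotropic unit normals
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    m <- cbind(r * cos(phi), r * sin(phi), z)
    b <- beam / sqrt(sum(beam^2))
    mean(abs(m %*% b))
  })
}

# Evaluate code under a temporary RNG state seeded with `seed`; restores the
# caller's RNG. `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 1009L + sum(utf8ToInt(as.character(stream))) %% 997L
}

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
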