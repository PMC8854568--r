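# broom-style tidiers for the fitted objects.

#' @export
tidy.edge_model_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @export
glance.edge_model_fit <- function(x, ...) {
  tibble::tibble(sigma_u = x$sigma_u, sigma_eps = x$sigma_eps,
                 variance_partition = x$variance_partition,
                 aic = tryCatch(AIC(x$fit), error = function(e) NA_real_),
                 convergence = x$convergence)
}

#' @export
tidy.hockey_fit <- function(x, ...) {
  tibble::tibble(term = c("breakpoint", "intercept", "slope1", "slope2"),
                 estimate = c(x$breakpoint, x$intercept, x$slope1, x$slope2))
}

#' @export
glance.hockey_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, sse_line = x$sse_line,
                 improvement = x$improvement, supported = x$supported,
                 n = x$n)
}

#' @export
tidy.phenology_fit <- function(x, ...) x$coefficients

#' @export
glance.phenology_fit <- function(x, ...) {
  tibble::tibble(model = x$model, method = x$method, AIC = x$aic,
                 logLik = x$logLik, sigma = x$varcomp$sigma,
                 sd_transect = x$varcomp$sd_transect,
                 sd_edge_in_transect = x$varcomp$sd_edge_in_transect,
                 singular = x$singular)
}

#' @export
tidy.permutation_envelope <- function(x, ...) x$coef_envelope

#' @export
tidy.strata_coupling <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "upper_canopy"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.strata_coupling <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, statistic = x$statistic,
                 p.value = x$p.value, n = x$n)
}
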