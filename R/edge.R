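# Edge effects on PAI: the asymptotic nonlinear mixed model
# PAI = beta0 + beta1 * exp(-beta2 * x) + u_transect + eps, the share of PAI
# variance carried by transects, a continuous two-segment ("hockey stick")
# breakpoint estimate of the edge-influence distance, and the categorical
# edge/interior split.

#' Classify distance to edge
#'
#' Edge if and only if `distance < threshold` (half-open `[0, threshold)`
#' convention: a column exactly at the threshold is interior).
#'
#' @param distance Distance to the forest margin, metres (>= 0).
#' @param threshold Edge distance threshold, metres.
#' @return Character vector `"edge"` / `"interior"`.
#' @export
classify_edge <- function(distance, threshold = 40) {
  abort_if(any(distance < 0, na.rm = TRUE), "distances must be >= 0")
  ifelse(distance < threshold, "edge", "interior")
}

# Profile the pooled (fixed-effects) SSE over beta2: for a given beta2 the
# model is linear in (beta0, beta1).
edge_profile_fit <- function(x, y, beta2) {
  X <- cbind(1, exp(-beta2 * x))
  fit <- lm.fit(X, y)
  list(beta = c(fit$coefficients, beta2), sse = sum(fit$residuals^2))
}

#' Fit the asymptotic edge-gradient mixed model
#'
#' Maximum-likelihood fit of `PAI = beta0 + beta1 * exp(-beta2 * x) + u_i +
#' eps` with a random intercept per transect. Starting values come from a
#' profile grid over `beta2` (linear solves for `beta0`, `beta1`); when the
#' profile solution is already an interpolating fit (noise-free data) it is
#' returned exactly with zero variance components, and when the nonlinear
#' mixed fit fails to converge from every start the profile/`nls` solution is
#' returned flagged. Reports the transect share of total variance,
#' `sigma_u^2 / (sigma_u^2 + sigma_eps^2)`.
#'
#' @param panel PAI panel tibble; rows to model (e.g. one stratum) should be
#'   pre-filtered.
#' @param response,distance_col,group Column names of the response, the
#'   distance to edge and the random-intercept grouping.
#' @param beta2_grid Candidate `beta2` values for the multi-start profile.
#' @return Object of class `edge_model_fit` with elements `beta` (named
#'   vector), `sigma_u`, `sigma_eps`, `variance_partition`, `convergence`,
#'   `fit` (the underlying nlme/nls object when available).
#' @export
fit_edge_model <- function(panel, response = "pai",
                           distance_col = "distance_to_edge",
                           group = "transect_id",
                           beta2_grid = seq(0.01, 0.5, length.out = 25)) {
  df <- data.frame(y = panel[[response]], x = panel[[distance_col]],
                   g = factor(panel[[group]]))
  df <- df[stats::complete.cases(df), ]
  abort_if(nlevels(droplevels(df$g)) < 2,
           "need >= 2 transects for the random intercept")

  prof <- lapply(beta2_grid, function(b2) edge_profile_fit(df$x, df$y, b2))
  sse <- vapply(prof, `[[`, numeric(1), "sse")
  best <- which.min(sse)
  # local refinement of the profile optimum
  lo <- beta2_grid[max(1, best - 1)]; hi <- beta2_grid[min(length(sse), best + 1)]
  b2_opt <- optimize(function(b2) edge_profile_fit(df$x, df$y, b2)$sse,
                     c(lo, hi))$minimum
  prof_best <- edge_profile_fit(df$x, df$y, b2_opt)
  start <- setNames(prof_best$beta, c("beta0", "beta1", "beta2"))

  if (prof_best$sse / nrow(df) < 1e-12) {
    return(new_edge_fit(start, 0, 0, NULL, "exact (noise-free profile fit)"))
  }

  order_starts <- order(sse)[seq_len(min(4, length(sse)))]
  starts <- c(list(start),
              lapply(order_starts, function(i)
                setNames(prof[[i]]$beta, c("beta0", "beta1", "beta2"))))
  for (st in starts) {
    fit <- try(nlme::nlme(y ~ b0 + b1 * exp(-b2 * x), data = df,
                          fixed = b0 + b1 + b2 ~ 1, random = b0 ~ 1 | g,
                          start = unname(st), method = "ML",
                          control = nlme::nlmeControl(maxIter = 200,
                                                      msMaxIter = 200,
                                                      returnObject = FALSE)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      beta <- setNames(nlme::fixef(fit), c("beta0", "beta1", "beta2"))
      vc <- nlme::VarCorr(fit)
      sigma_u <- suppressWarnings(as.numeric(vc["b0", "StdDev"]))
      sigma_eps <- fit$sigma
      return(new_edge_fit(beta, sigma_u, sigma_eps, fit, "converged"))
    }
  }
  # fall back to a fixed-effects nonlinear least squares fit
  nfit <- try(nls(y ~ b0 + b1 * exp(-b2 * x), data = df,
                  start = as.list(start)), silent = TRUE)
  if (!inherits(nfit, "try-error")) {
    beta <- setNames(coef(nfit), c("beta0", "beta1", "beta2"))
    return(new_edge_fit(beta, 0, summary(nfit)$sigma, nfit,
                        "nlme failed; fixed-effects nls fallback"))
  }
  new_edge_fit(start, 0, sqrt(prof_best$sse / nrow(df)), NULL,
               "non-convergence; profile grid-search best point")
}

new_edge_fit <- function(beta, sigma_u, sigma_eps, fit, convergence) {
  vp <- if (sigma_u == 0 && sigma_eps == 0) 0 else
    sigma_u^2 / (sigma_u^2 + sigma_eps^2)
  structure(list(beta = beta, sigma_u = sigma_u, sigma_eps = sigma_eps,
                 variance_partition = vp, convergence = convergence,
                 fit = fit),
            class = "edge_model_fit")
}

#' @export
print.edge_model_fit <- function(x, ...) {
  cat("<edge_model_fit> PAI = beta0 + beta1 * exp(-beta2 * x) + u + eps\n")
  cat(sprintf("  beta0 = %.4f, beta1 = %.4f, beta2 = %.4f m^-1\n",
              x$beta[1], x$beta[2], x$beta[3]))
  cat(sprintf("  sigma_u = %.4f, sigma_eps = %.4f, transect variance share = %.1f%%\n",
              x$sigma_u, x$sigma_eps, 100 * x$variance_partition))
  cat("  status:", x$convergence, "\n")
  invisible(x)
}

#' Fit a continuous two-segment (hockey-stick) model
#'
#' Least squares over candidate breakpoints on a 0.5 m lattice followed by
#' local refinement; the two segments are constrained continuous at the
#' breakpoint. Ties in SSE break toward the smaller breakpoint. When the best
#' two-segment fit improves the single-line SSE by less than
#' `support_improvement` the breakpoint is flagged unsupported.
#'
#' @param panel PAI panel tibble (pre-filtered rows).
#' @param response,distance_col Column names.
#' @param lattice Candidate breakpoint spacing, metres.
#' @param min_side Minimum points strictly on each side of a candidate.
#' @param support_improvement Minimum relative SSE improvement over the
#'   single-line fit for the breakpoint to count as supported.
#' @return Object of class `hockey_fit`: `breakpoint`, `intercept`, `slope1`,
#'   `slope2` (the second segment is `y(bp) + slope2 * (x - bp)`), `sse`,
#'   `sse_line`, `improvement`, `supported`.
#' @export
fit_hockey_stick <- function(panel, response = "pai",
                             distance_col = "distance_to_edge",
                             lattice = 0.5, min_side = 3,
                             support_improvement = 0.01) {
  x <- panel[[distance_col]]; y <- panel[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  abort_if(length(unique(x)) < 10, "need >= 10 distinct distances")

  sse_at <- function(bp) {
    X <- cbind(1, x, pmax(x - bp, 0))
    sum(lm.fit(X, y)$residuals^2)
  }
  xs <- sort(unique(x))
  cand <- seq(ceiling(min(x) / lattice) * lattice,
              floor(max(x) / lattice) * lattice, by = lattice)
  cand <- cand[vapply(cand, function(b)
    sum(xs < b) >= min_side && sum(xs > b) >= min_side, logical(1))]
  abort_if(length(cand) == 0,
           "degenerate fit: fewer than min_side points on one side of every candidate")
  sse <- vapply(cand, sse_at, numeric(1))
  best <- which.min(sse) # first minimum = smallest breakpoint on ties
  bp <- optimize(sse_at, c(cand[max(1, best - 1)],
                           cand[min(length(cand), best + 1)]))$minimum
  if (sse_at(bp) > sse[best] + 1e-12) bp <- cand[best]

  X <- cbind(1, x, pmax(x - bp, 0))
  fit <- lm.fit(X, y)
  co <- fit$coefficients
  sse_best <- sum(fit$residuals^2)
  line <- lm.fit(cbind(1, x), y)
  sse_line <- sum(line$residuals^2)
  # a line already interpolating the data (to numerical noise) has no break
  improvement <- if (sse_line > 1e-10 * sum(y^2)) 1 - sse_best / sse_line
                 else 0
  structure(list(breakpoint = bp, intercept = co[1], slope1 = co[2],
                 slope2 = co[2] + co[3], sse = sse_best,
                 sse_line = sse_line, improvement = improvement,
                 supported = improvement >= support_improvement,
                 n = length(x)),
            class = "hockey_fit")
}

#' @export
print.hockey_fit <- function(x, ...) {
  cat("<hockey_fit> continuous two-segment least squares\n")
  if (x$supported)
    cat(sprintf("  breakpoint %.2f m; slopes %.4f -> %.4f; SSE improvement %.1f%%\n",
                x$breakpoint, x$slope1, x$slope2, 100 * x$improvement))
  else
    cat(sprintf("  no supported breakpoint (SSE improvement %.2f%% < threshold)\n",
                100 * x$improvement))
  invisible(x)
}
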