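# Seasonal phenology models for stratum PAI: linear mixed models with
# categorical survey time, the edge/interior class and their interaction as
# fixed effects and edge class nested within transect as random intercepts;
# AIC-based structure selection; subsample-refit ("permutation") envelopes
# for coefficients and predicted cell means; and the understory--upper-canopy
# coupling regression on survey means.

phenology_fixed_formula <- function(model) {
  switch(model,
         interaction = pai ~ time * edge_class,
         additive = pai ~ time + edge_class,
         edge_plus_interaction = pai ~ edge_class + time:edge_class,
         stop("unknown model structure: ", model))
}

#' Fit a phenology linear mixed model
#'
#' Fits stratum PAI against categorical survey time, edge class and
#' (depending on `model`) their interaction, with random intercepts for edge
#' class nested within transect and optionally a distinct residual variance
#' multiplier per edge class (a varIdent-style weighting). Maximum likelihood
#' is the default so AICs are comparable across fixed-effect structures; use
#' `method = "REML"` to refit a selected model for reporting. On data with
#' (numerically) zero residual noise the mixed fit is degenerate and the
#' model falls back to the exact ordinary-least-squares solution with zero
#' variance components.
#'
#' @param panel PAI panel tibble.
#' @param stratum Which stratum to model (`"understory"`, `"upper_canopy"`,
#'   `"total"`).
#' @param model Fixed-effect structure: `"interaction"` (time + edge +
#'   time x edge), `"additive"`, or `"edge_plus_interaction"` (edge and
#'   time x edge without the time main effect).
#' @param heteroscedastic `FALSE` for a single residual variance, or
#'   `"edge_class"` for per-edge-class residual multipliers.
#' @param method `"ML"` or `"REML"`.
#' @return Object of class `phenology_fit`: `coefficients` tibble (term,
#'   estimate, se, df, statistic, p.value), `aic`, `logLik`, `varcomp`,
#'   `cell_means` (predicted PAI per time x edge cell with SE), `model`,
#'   `converged`, plus the underlying `nlme::lme` (or `lm`) object.
#' @export
fit_phenology_lme <- function(panel, stratum = "understory",
                              model = c("interaction", "additive",
                                        "edge_plus_interaction"),
                              heteroscedastic = FALSE, method = "ML") {
  model <- match.arg(model)
  df <- panel[panel$stratum == stratum, , drop = FALSE]
  abort_if(nrow(df) == 0, "no rows for the requested stratum")
  df <- data.frame(pai = df$pai,
                   time = droplevels(factor(df$time %||% df$survey_time)),
                   edge_class = factor(df$edge_class,
                                       levels = c("interior", "edge")),
                   transect = factor(df$transect_id))
  df$edge_class <- droplevels(df$edge_class)
  abort_if(nlevels(df$time) < 2, "time needs >= 2 levels")
  fixed <- phenology_fixed_formula(model)

  # zero-noise degenerate case: exact OLS solution
  ols <- lm(fixed, data = df)
  if (mean(resid(ols)^2) < 1e-16) {
    return(new_phenology_fit(ols, df, model, method, ols_fallback = TRUE))
  }

  weights <- if (identical(heteroscedastic, "edge_class") &&
                 nlevels(df$edge_class) > 1)
    nlme::varIdent(form = ~ 1 | edge_class) else NULL
  fit <- try(nlme::lme(fixed, random = ~ 1 | transect / edge_class,
                       weights = weights, data = df, method = method,
                       control = nlme::lmeControl(maxIter = 200,
                                                  msMaxIter = 200,
                                                  opt = "optim",
                                                  returnObject = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(new_phenology_fit(ols, df, model, method, ols_fallback = TRUE,
                             note = "lme failed; OLS fallback"))
  new_phenology_fit(fit, df, model, method)
}

new_phenology_fit <- function(fit, df, model, method, ols_fallback = FALSE,
                              note = NULL) {
  is_lme <- inherits(fit, "lme")
  if (is_lme) {
    tt <- summary(fit)$tTable
    coefs <- tibble::tibble(term = rownames(tt), estimate = tt[, "Value"],
                            se = tt[, "Std.Error"], df = tt[, "DF"],
                            statistic = tt[, "t-value"],
                            p.value = tt[, "p-value"])
    vc <- suppressWarnings(nlme::VarCorr(fit))
    sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
    varcomp <- list(sd_transect = sds[2], sd_edge_in_transect = sds[4],
                    sigma = fit$sigma)
    vs <- fit$modelStruct$varStruct
    if (!is.null(vs))
      varcomp$var_multipliers <- coef(vs, unconstrained = FALSE,
                                      allCoef = TRUE)
    beta <- nlme::fixef(fit)
    V <- vcov(fit)
    aic <- AIC(fit); ll <- as.numeric(logLik(fit))
    singular <- any(sds[c(2, 4)] < 1e-6 * fit$sigma, na.rm = TRUE)
  } else {
    sm <- suppressWarnings(summary(fit))$coefficients
    keep <- rownames(sm)
    coefs <- tibble::tibble(term = keep, estimate = sm[, 1], se = sm[, 2],
                            df = fit$df.residual, statistic = sm[, 3],
                            p.value = sm[, 4])
    varcomp <- list(sd_transect = 0, sd_edge_in_transect = 0,
                    sigma = sqrt(mean(resid(fit)^2)))
    beta <- coef(fit)
    V <- suppressWarnings(vcov(fit))
    aic <- AIC(fit); ll <- as.numeric(logLik(fit))
    singular <- TRUE
  }
  # predicted marginal means per time x edge cell (population level)
  cells <- expand.grid(time = factor(levels(df$time), levels = levels(df$time)),
                       edge_class = factor(levels(df$edge_class),
                                           levels = levels(df$edge_class)))
  X <- stats::model.matrix(stats::delete.response(stats::terms(
    phenology_fixed_formula(model))), data = cells)
  X <- X[, names(beta)[!is.na(beta)], drop = FALSE]
  b <- beta[!is.na(beta)]
  pred <- unname(drop(X %*% b))
  se <- sqrt(pmax(0, rowSums((X %*% V) * X)))
  cell_means <- tibble::tibble(time = cells$time,
                               edge_class = cells$edge_class,
                               pai = pred, se = se)
  structure(list(coefficients = coefs, aic = aic, logLik = ll,
                 varcomp = varcomp, cell_means = cell_means, model = model,
                 method = method, converged = TRUE, singular = singular,
                 ols_fallback = ols_fallback, note = note, fit = fit,
                 data = df),
            class = "phenology_fit")
}

#' @export
print.phenology_fit <- function(x, ...) {
  cat(sprintf("<phenology_fit> structure '%s' (%s%s), AIC %.1f\n", x$model,
              x$method, if (x$ols_fallback) ", OLS fallback" else "", x$aic))
  cat(sprintf("  sd(transect) %.3f, sd(edge in transect) %.3f, sigma %.3f%s\n",
              x$varcomp$sd_transect, x$varcomp$sd_edge_in_transect,
              x$varcomp$sigma,
              if (x$singular) " [variance at boundary]" else ""))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Test the time x edge interaction
#'
#' Marginal F-test of the interaction term from the fitted interaction
#' model's conditional ANOVA (containment denominator degrees of freedom).
#'
#' @param fit A `phenology_fit` with `model = "interaction"`.
#' @return Tibble with `statistic`, `num_df`, `den_df`, `p.value`.
#' @export
interaction_test <- function(fit) {
  stopifnot(inherits(fit, "phenology_fit"))
  abort_if(fit$model != "interaction",
           "interaction test requires the interaction structure")
  if (inherits(fit$fit, "lme")) {
    an <- anova(fit$fit)
    row <- grep(":", rownames(an))
    tibble::tibble(statistic = an[row, "F-value"],
                   num_df = an[row, "numDF"], den_df = an[row, "denDF"],
                   p.value = an[row, "p-value"])
  } else {
    an <- anova(fit$fit)
    row <- grep(":", rownames(an))
    tibble::tibble(statistic = an[row, "F value"], num_df = an[row, "Df"],
                   den_df = an["Residuals", "Df"],
                   p.value = an[row, "Pr(>F)"])
  }
}

#' Select among candidate phenology structures by AIC
#'
#' All candidates must be fitted on the same data by maximum likelihood.
#' Returns the lowest-AIC fit; candidates within `delta_equiv` AIC of the
#' best are treated as equivalent and the simplest (fewest fixed-effect
#' terms) is preferred. Non-converged candidates are dropped with a warning.
#'
#' @param fits Named list of `phenology_fit` objects.
#' @param delta_equiv AIC difference treated as a tie.
#' @return List with `best` (a `phenology_fit`), `best_name`, and `table`
#'   (tibble of model, aic, delta_aic, n_fixed).
#' @export
select_model <- function(fits, delta_equiv = 2) {
  stopifnot(length(fits) >= 1)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!ok)) warning("dropping non-converged candidate(s): ",
                        paste(names(fits)[!ok], collapse = ", "))
  fits <- fits[ok]
  abort_if(length(fits) == 0, "no converged candidates")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  npar <- vapply(fits, function(f) nrow(f$coefficients), numeric(1))
  tab <- tibble::tibble(model = names(fits), aic = aic,
                        delta_aic = aic - min(aic), n_fixed = npar) |>
    dplyr::arrange(.data$aic)
  tied <- tab$model[tab$delta_aic < delta_equiv]
  best_name <- tied[which.min(npar[tied])]
  list(best = fits[[best_name]], best_name = best_name, table = tab)
}

#' Subsample-refit envelope for phenology models
#'
#' Refits the model on `n` random calibration subsets holding `split` of the
#' rows of each transect x edge x time design cell (so no cell is ever lost),
#' and forms per-coefficient and per-predicted-cell envelopes from the 2.5%
#' and 97.5% quantiles of the refit distribution. Because estimates from
#' overlapping `split`-fraction subsets scatter less than the full sampling
#' variability, the default `scale = "jackknife"` recentres the quantile
#' deviations on the full-data fit and inflates them by the delete-d
#' jackknife factor `sqrt(split / (1 - split))`, giving envelopes with
#' near-nominal coverage; `scale = "raw"` returns the unscaled quantiles of
#' the refit distribution.
#'
#' @inheritParams fit_phenology_lme
#' @param n Number of resamples.
#' @param split Calibration fraction in (0, 1).
#' @param seed Integer seed; identical seed gives identical quantiles.
#' @param scale `"jackknife"` or `"raw"`.
#' @param max_redraw Redraw attempts if a resample loses a design cell.
#' @return Object of class `permutation_envelope`: `coef_envelope` (term,
#'   estimate, lower, upper), `cell_envelope` (time, edge_class, pai, lower,
#'   upper), `draws` (coefficient matrix), `n`, `split`, `seed`, `scale`.
#' @export
permutation_ci <- function(panel, stratum = "understory",
                           model = "interaction", heteroscedastic = FALSE,
                           n = 200, split = 0.8, seed = 1L,
                           scale = c("jackknife", "raw"), max_redraw = 10) {
  scale <- match.arg(scale)
  abort_if(n < 2, "need n >= 2 resamples")
  abort_if(split <= 0 || split >= 1, "split must be in (0, 1)")
  full <- fit_phenology_lme(panel, stratum, model,
                            heteroscedastic = heteroscedastic)
  rows <- which(panel$stratum == stratum)
  sub <- panel[rows, ]
  cell <- paste(sub$transect_id, sub$edge_class,
                as.character(sub$time %||% sub$survey_time))
  cells <- split(seq_along(cell), cell)

  draw_fit <- function() {
    for (attempt in seq_len(max_redraw)) {
      idx <- unlist(lapply(cells, function(ii) {
        k <- max(1L, round(split * length(ii)))
        if (length(ii) == 1) ii else sample(ii, k)
      }), use.names = FALSE)
      f <- try(fit_phenology_lme(sub[idx, ], stratum, model,
                                 heteroscedastic = heteroscedastic),
               silent = TRUE)
      if (!inherits(f, "try-error") &&
          nrow(f$coefficients) == nrow(full$coefficients)) return(f)
    }
    stop("a resample kept losing design cells after ", max_redraw,
         " attempts", call. = FALSE)
  }

  fits <- with_seed(seed, replicate(n, draw_fit(), simplify = FALSE))
  coefs <- do.call(rbind, lapply(fits, function(f) f$coefficients$estimate))
  colnames(coefs) <- full$coefficients$term
  cellp <- do.call(rbind, lapply(fits, function(f) f$cell_means$pai))

  envelope <- function(center, draws) {
    if (scale == "raw") {
      lo <- apply(draws, 2, quantile, 0.025, names = FALSE)
      hi <- apply(draws, 2, quantile, 0.975, names = FALSE)
    } else {
      f <- sqrt(split / (1 - split))
      dev <- sweep(draws, 2, colMeans(draws))
      lo <- center + f * apply(dev, 2, quantile, 0.025, names = FALSE)
      hi <- center + f * apply(dev, 2, quantile, 0.975, names = FALSE)
    }
    list(lower = lo, upper = hi)
  }
  ce <- envelope(full$coefficients$estimate, coefs)
  pe <- envelope(full$cell_means$pai, cellp)
  structure(list(
    coef_envelope = tibble::tibble(term = full$coefficients$term,
                                   estimate = full$coefficients$estimate,
                                   lower = ce$lower, upper = ce$upper),
    cell_envelope = dplyr::mutate(full$cell_means, lower = pe$lower,
                                  upper = pe$upper),
    draws = coefs, n = n, split = split, seed = seed, scale = scale,
    model = model, stratum = stratum),
    class = "permutation_envelope")
}

#' @export
print.permutation_envelope <- function(x, ...) {
  cat(sprintf("<permutation_envelope> %d refits, %.0f/%.0f split, %s scaling\n",
              x$n, 100 * x$split, 100 * (1 - x$split), x$scale))
  print(x$coef_envelope, n = 6)
  invisible(x)
}

#' Understory--upper-canopy coupling regression
#'
#' Ordinary least squares of per-survey mean understory PAI on per-survey
#' mean upper canopy PAI (one point per survey), the test of whether
#' understory greening tracks upper-canopy loss. Accepts either two aligned
#' vectors of survey means or a PAI panel (optionally filtered to one edge
#' class) from which the survey means are computed.
#'
#' @param understory Numeric vector of survey-mean understory PAI, or a PAI
#'   panel tibble.
#' @param canopy Numeric vector of survey-mean upper canopy PAI (ignored if
#'   `understory` is a panel).
#' @param edge_class Optional edge class filter when a panel is given.
#' @param exclude_survey Optional survey time(s) to drop (sensitivity runs).
#' @return Object of class `strata_coupling`: `slope`, `intercept`,
#'   `r.squared`, `statistic` (F), `p.value`, `n`, and the survey means.
#' @export
strata_coupling <- function(understory, canopy = NULL, edge_class = NULL,
                            exclude_survey = NULL) {
  if (is.data.frame(understory)) {
    panel <- understory
    if (!is.null(edge_class))
      panel <- panel[panel$edge_class == edge_class, ]
    if (!is.null(exclude_survey))
      panel <- panel[!panel$survey_time %in% exclude_survey, ]
    means <- panel |>
      dplyr::filter(.data$stratum %in% c("understory", "upper_canopy")) |>
      dplyr::group_by(.data$survey_time, .data$stratum) |>
      dplyr::summarise(pai = mean(.data$pai), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "stratum", values_from = "pai")
    understory <- means$understory
    canopy <- means$upper_canopy
    surveys <- means$survey_time
  } else {
    surveys <- seq_along(understory)
    if (!is.null(exclude_survey)) {
      keep <- !surveys %in% exclude_survey
      understory <- understory[keep]; canopy <- canopy[keep]
      surveys <- surveys[keep]
    }
  }
  abort_if(length(understory) < 3, "need >= 3 paired survey means")
  fit <- lm(understory ~ canopy)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r.squared = sm$r.squared,
                 statistic = unname(fstat[1]),
                 p.value = unname(pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE)),
                 n = length(understory),
                 means = tibble::tibble(survey_time = surveys,
                                        understory = understory,
                                        upper_canopy = canopy),
                 fit = fit),
            class = "strata_coupling")
}

#' @export
print.strata_coupling <- function(x, ...) {
  cat(sprintf("<strata_coupling> understory = %.3f %+.3f x upper canopy\n",
              x$intercept, x$slope))
  cat(sprintf("  R2 = %.3f, F = %.2f, p = %.3g (n = %d surveys)\n",
              x$r.squared, x$statistic, x$p.value, x$n))
  invisible(x)
}
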