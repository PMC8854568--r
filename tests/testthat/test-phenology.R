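# Phenology mixed models, AIC selection, permutation envelopes, coupling.

# compact study-like design: 2 edge-spanning transects + 1 interior transect
phen_design <- function(n_times = 6, sd_transect = 0.15,
                        sd_edge_within = 0.08,
                        sd_resid = c(edge = 0.4, interior = 0.3),
                        cell_effects = NULL, seasonal = NULL,
                        column_spacing = 5, edge_profile = "asymptotic") {
  panel_design(times = seq_len(n_times),
               transects = tibble::tibble(
                 transect_id = c("T1", "T2", "T3"),
                 x_min = c(0, 0, 500), x_max = c(100, 100, 530)),
               column_spacing = column_spacing, edge_profile = edge_profile,
               seasonal_multipliers = seasonal, cell_effects = cell_effects,
               sd_transect = sd_transect, sd_edge_within = sd_edge_within,
               sd_resid = sd_resid)
}

test_that("noise-free panels give exact coefficients and zero envelopes", {
  ce <- tibble::tibble(survey = 3L, edge_class = "edge",
                       stratum = "understory", delta = -0.25)
  d <- phen_design(n_times = 4, sd_transect = 0, sd_edge_within = 0,
                   sd_resid = 0, cell_effects = ce, edge_profile = "none")
  p <- simulate_pai_panel(d, seed = 1)
  fit <- fit_phenology_lme(p, "understory", "interaction")
  expect_true(fit$ols_fallback)
  # the only fixed-effect signal is the injected interaction cell
  cm <- fit$cell_means
  base <- cm$pai[cm$edge_class == "edge" & cm$time != "3"]
  expect_equal(unname(cm$pai[cm$edge_class == "edge" & cm$time == "3"]),
               unname(unique(base)[1]) - 0.25, tolerance = 1e-8)
  env <- permutation_ci(p, "understory", "interaction", n = 10, seed = 2)
  expect_lt(max(env$coef_envelope$upper - env$coef_envelope$lower), 1e-8)
})

test_that("an injected interaction effect is recovered within its envelope", {
  delta <- -0.25
  ce <- tibble::tibble(survey = 4L, edge_class = "edge",
                       stratum = "upper_canopy", delta = delta)
  p <- simulate_pai_panel(phen_design(n_times = 6, cell_effects = ce),
                          seed = 7)
  fit <- fit_phenology_lme(p, "upper_canopy", "interaction")
  # difference-in-differences at the injected cell
  cm <- fit$cell_means
  did <- (cm$pai[cm$edge_class == "edge" & cm$time == "4"] -
            cm$pai[cm$edge_class == "edge" & cm$time == "1"]) -
    (cm$pai[cm$edge_class == "interior" & cm$time == "4"] -
       cm$pai[cm$edge_class == "interior" & cm$time == "1"])
  expect_lt(abs(did - delta), 0.15)
  env <- permutation_ci(p, "upper_canopy", "interaction", n = 60, seed = 8)
  term <- grep("^time4.*edge$|edge.*time4$", env$coef_envelope$term,
               value = TRUE)
  row <- env$coef_envelope[env$coef_envelope$term == term, ]
  expect_true(row$lower <= delta && delta <= row$upper)
})

test_that("model selection prefers the true structure and breaks ties simply", {
  # strong interaction truth
  ce <- tidyr::expand_grid(survey = 4:6, edge_class = "edge",
                           stratum = "understory") |>
    dplyr::mutate(delta = -0.6)
  p <- simulate_pai_panel(phen_design(n_times = 6, cell_effects = ce),
                          seed = 11)
  fits <- lapply(c(interaction = "interaction", additive = "additive"),
                 function(m) fit_phenology_lme(p, "understory", m))
  sel <- select_model(fits)
  expect_equal(sel$best_name, "interaction")
  # additive truth: additive preferred (tie broken toward fewer terms)
  p0 <- simulate_pai_panel(phen_design(n_times = 6), seed = 12)
  fits0 <- lapply(c(interaction = "interaction", additive = "additive"),
                  function(m) fit_phenology_lme(p0, "understory", m))
  sel0 <- select_model(fits0)
  expect_equal(sel0$best_name, "additive")
  # single candidate returned as-is
  one <- select_model(fits0["additive"])
  expect_equal(one$best_name, "additive")
})

test_that("AIC ordering is invariant to a constant response offset", {
  p <- simulate_pai_panel(phen_design(n_times = 5), seed = 21)
  p2 <- dplyr::mutate(p, pai = pai + 100)
  d1 <- fit_phenology_lme(p, "understory", "interaction")$aic -
    fit_phenology_lme(p, "understory", "additive")$aic
  d2 <- fit_phenology_lme(p2, "understory", "interaction")$aic -
    fit_phenology_lme(p2, "understory", "additive")$aic
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("varIdent-style weighting estimates per-group residual multipliers", {
  p <- simulate_pai_panel(phen_design(
    n_times = 5, sd_resid = c(edge = 0.8, interior = 0.3),
    column_spacing = 2), seed = 31)
  fit <- fit_phenology_lme(p, "understory", "interaction",
                           heteroscedastic = "edge_class")
  m <- fit$varcomp$var_multipliers
  expect_false(is.null(m))
  ratio <- max(m) / min(m)
  expect_gt(ratio, 1.8) # truth 0.8 / 0.3 = 2.67
  expect_lt(ratio, 4)
})

test_that("permutation envelopes are reproducible and seed-sensitive", {
  p <- simulate_pai_panel(phen_design(n_times = 4), seed = 41)
  e1 <- permutation_ci(p, "understory", "additive", n = 20, seed = 5)
  e2 <- permutation_ci(p, "understory", "additive", n = 20, seed = 5)
  e3 <- permutation_ci(p, "understory", "additive", n = 20, seed = 6)
  expect_identical(e1$coef_envelope, e2$coef_envelope)
  expect_false(identical(e1$coef_envelope, e3$coef_envelope))
  expect_true(all(e1$coef_envelope$lower <= e1$coef_envelope$estimate + 1e-9))
  expect_true(all(e1$coef_envelope$upper >= e1$coef_envelope$estimate - 1e-9))
})

test_that("perfect anticorrelation gives slope -1 and R2 = 1", {
  u <- seq(8.2, 7.6, length.out = 11)
  cc <- seq(3.0, 3.6, length.out = 11)
  sc <- suppressWarnings(strata_coupling(u, cc))
  expect_equal(sc$slope, -1, tolerance = 1e-9)
  expect_equal(sc$r.squared, 1, tolerance = 1e-9)
})

test_that("independent survey means give near-zero R2", {
  r2 <- vapply(1:100, function(s) with_seed(s, {
    strata_coupling(rnorm(11, 8, 0.2), rnorm(11, 3.3, 0.1))$r.squared
  }), numeric(1))
  expect_lt(median(r2), 0.15)
})

test_that("coupling accepts panels, filters edge class, drops surveys", {
  p <- simulate_pai_panel(phen_design(
    n_times = 6, seasonal = default_seasonal_multipliers()), seed = 51)
  sc <- strata_coupling(p, edge_class = "interior")
  expect_equal(sc$n, 6)
  sc2 <- strata_coupling(p, edge_class = "interior",
                         exclude_survey = sort(unique(p$survey_time))[1])
  expect_equal(sc2$n, 5)
  expect_error(strata_coupling(c(1, 2), c(3, 4)), ">= 3")
})

test_that("the interaction F-test is roughly calibrated under the null", {
  pvals <- vapply(1:60, function(s) {
    p <- simulate_pai_panel(phen_design(n_times = 4), seed = 6000 + s)
    interaction_test(fit_phenology_lme(p, "understory",
                                       "interaction"))$p.value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.0)
  expect_lt(rate, 0.15)
})

test_that("phenology fixed effects agree with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  p <- simulate_pai_panel(phen_design(n_times = 4, edge_profile = "none"),
                          seed = 77)
  ours <- fit_phenology_lme(p, "understory", "interaction", method = "REML")
  df <- ours$data
  ref <- lme4::lmer(pai ~ time * edge_class + (1 | transect / edge_class),
                    data = df, REML = TRUE)
  expect_equal(unname(ours$coefficients$estimate),
               unname(lme4::fixef(ref)), tolerance = 1e-3)
})
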