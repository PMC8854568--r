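---
title: "Methods: voxel-based canopy phenology from terrestrial laser scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-based canopy phenology from terrestrial laser scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyphen)
```

# The problem

Repeat terrestrial laser scanning (TLS) of a forest stand yields, for every
survey, millions of laser pulses with up to eight recorded returns each. From
these the package estimates a voxelised field of **plant area density** (PAD,
one-sided plant area per unit volume, m² m⁻³), sums it into per-column
**plant area index** (PAI, m² m⁻²) split at a strata boundary into understory
and upper canopy, and then asks the ecological questions: how does PAI decay
with distance to a forest-fragment edge, where is the vertical boundary
between strata that move in opposite directions through the dry season, how
do the strata's seasonal trajectories differ between edge and interior
forest, and how tightly is understory greening coupled to upper-canopy loss.
Because deposited field data are not required, every stage is exercised
against a synthetic forest whose truth is known, so the whole chain is
verified by parameter recovery.

# Gap-fraction model and the attenuation estimator

Within a voxel, vegetation elements are treated as randomly distributed
(within-voxel clumping neglected), so the probability that a beam travels a
path of length $l$ without interception is

$$P(\theta, l) = \exp(-\lambda_\theta\, l),$$

with $\lambda_\theta$ (m⁻¹) the directional attenuation coefficient. PAD
follows as $\mathrm{PAD} = \lambda_\theta / G(\theta)$ where the projection
function $G$ is fixed at $0.5$, exact for a spherical leaf-angle
distribution ($E\lvert\cos\angle\rvert = 1/2$ for any beam direction;
`g_spherical()` verifies this by Monte Carlo).

Each pulse is traced through the 1-m voxel grid. A pulse with $k$ recorded
returns splits its beam section equally, $1/k$ per return; the weight
entering a voxel is one minus the weights already deposited at earlier hits.
Per voxel the accumulator keeps the entering weight, the intercepted weight,
the weighted *free path* (voxel entry to hit, for intercepted fractions),
the weighted *survivor path* (full within-voxel path of fractions that pass
through, censored at a terminal ground return), and the weighted *potential*
path. The free-path-length estimator is the maximiser of the weighted
censored-exponential log-likelihood

$$\ell(\lambda) = \sum_{\text{hits}} w(\log\lambda - \lambda z)
  - \sum_{\text{survivors}} w\,\lambda\, l,
  \qquad
  \hat\lambda = \frac{\sum_{\text{hits}} w}
  {\sum w z + \sum w l},$$

capped at `cap_lambda` (default 8 m⁻¹, PAD 16 m² m⁻³) when the path
denominator vanishes in a fully occluding voxel. Voxels never entered by any
beam fraction are flagged unsampled rather than zero-filled. A Beer–Lambert
ratio estimator, $-\log(\text{surviving}/\text{entering})$ divided by the
mean weighted potential path, is provided as a cross-check only. The two
agree on homogeneous, densely sampled voxels with constant within-voxel
paths; under heterogeneous path lengths (isotropic beams) the ratio
estimator carries a Jensen-type bias of a few percent, which is why the
likelihood estimator is the default and the consistency test uses
axis-aligned bundles.

Ground returns terminate a pulse: they are excluded from vegetation
interception and censor the surviving fraction's path at the ground hit.
Pulses with no return at all are kept (as `return_index = 0` marker rows)
because their full survivor path is informative.

## Ray traversal

Traversal uses incremental (Amanatides–Woo style) grid stepping with
half-open `[entry, exit)` segments; a return exactly on a shared voxel face
belongs to the voxel being entered, and segment lengths reproduce the
in-grid path length to 10⁻⁹ m. The test suite checks traversal against a
dense-sampling oracle that bins 5–10 thousand equally spaced points per ray.

# The synthetic forest

`scene_config()` + `build_truth_grid()` define truth PAD fields with the
structure the downstream analyses assume:

* two vertical strata split at 15 m above ground, with baseline stratum PAD
  means 0.54 (understory) and 0.165 (upper canopy) m² m⁻³, i.e. interior
  column PAI 8.1 + 3.3 = 11.4 m² m⁻² — chosen so the emulated relative
  declines (5.3% ≙ 0.43 m² m⁻² understory; 7.6% ≙ 0.25 m² m⁻² upper canopy)
  are internally consistent;
* an asymptotic edge gradient: column PAI follows
  $\beta_0 + \beta_1 e^{-\beta_2 x}$ in distance-to-edge $x$, applied as the
  dimensionless PAD multiplier
  $(\beta_0 + \beta_1 e^{-\beta_2 x})/\beta_0$ with defaults
  $(11.4, -1.7, 0.08\ \mathrm{m^{-1}})$, a ~15% deficit at the margin
  decaying on a 12.5 m length scale;
* per-survey multiplicative seasonal anomalies per stratum × edge class
  (`default_seasonal_multipliers()`): eleven fortnightly surveys
  April–October with a 40-day autumn-of-April gap. The interior understory
  bottoms out at 0.947 in late July and recovers (overshooting slightly to
  1.028 as the canopy sheds); the interior upper canopy is near-stable (a
  small mid-season flush to ~1.02) before dropping to 0.924 at the final
  survey; edges hold a mild aseasonal understory deficit (−3.4% from July)
  and an early, persistent canopy loss (−6% by mid-July). Under these
  trajectories the interior survey means of the two strata are negatively
  coupled with deterministic R² = 0.824 and slope ≈ −2; with the April
  anchor (both strata at baseline) fixed and the decline magnitudes
  honoured, a survey-mean R² much above this is not attainable, so ~0.82 is
  the emulated coupling strength;
* per-voxel lognormal heterogeneity with CV 0.3 (mean 1), making recovered
  fields realistically rough; deterministic per config seed and survey.

Survey simulation inverts the gap-fraction model exactly: a target optical
depth $-\log U$ is drawn per pulse and consumed along the traversal. In
`multi_return` mode the beam continues past a hit with probability
`p_continue` (default 0.5) up to eight returns, and recorded returns then
share the section equally — deliberately the *estimator's* split rule, not a
physical radiometric model; `single_return` mode is the unbiasedness test
bed. Scanner layouts default to the field protocol (scans every 5 m in three
lines, 30–130° zenith window plus a tilted companion scan, 350 m range);
angular resolution is the knob that scales pulse counts, and desk-scale runs
use 800–4000 mdeg instead of the instrument's 40 mdeg.

What the generator does **not** emulate: beam divergence (rays are lines,
the "beam section" enters only through fractions), radiometric intensity,
occlusion artefacts from wind or co-registration error, within-voxel
clumping, and leaf/wood separation. Passing tests therefore demonstrate that
the estimation chain inverts its own generative model at realistic scales —
not that field PAD is unbiased under instrument effects the model excludes.

`simulate_pai_panel()` bypasses ray tracing and draws PAI panels directly
from the fixed-effect structure (baseline × edge profile × seasonal
multiplier + injected cell effects) plus per-stratum transect and
edge-within-transect random intercepts and heteroscedastic residual noise
(defaults: SD 0.25 and 0.12 m² m⁻² for the intercepts; residual SD 0.45
edge / 0.35 interior). Total-PAI rows are the exact sum of the stratum
draws, so column additivity holds row by row.

# Derived canopy products

The DTM is inverse-distance-weighted (power 2, 10 nearest neighbours) onto a
0.5 m raster from ground returns; exact hits pass through verbatim. Height
normalisation shifts each column by its local ground elevation rounded to
whole voxels, conserving column PAD mass exactly. Column PAI sums
PAD × voxel height per stratum, excluding unsampled voxels; columns with
under 80% of voxels sampled (a named knob, `min_sampled_frac`) are omitted
with a count. The strata boundary is detected on the vertical profile of
mean PAD change between two surveys: a 3-bin moving average is smoothed over
the profile and the positive-to-negative zero crossing is interpolated
linearly; among multiple crossings the one maximising sign consistency
(fraction of bins positive below, negative above) wins, with the crossing
count reported, and an all-positive or flat profile returns an explicit
no-boundary result distinct from 0 m.

# Edge-effect models

The asymptotic mixed model
$\mathrm{PAI} = \beta_0 + \beta_1 e^{-\beta_2 x} + u_i + \varepsilon_i$
(random transect intercept) is fitted by maximum likelihood with `nlme`.
Because nonlinear mixed fits are initialisation-sensitive, starting values
come from a profile grid over $\beta_2 \in [0.01, 0.5]$ m⁻¹ with linear
solves for $\beta_0, \beta_1$, refined locally; if the profile solution
already interpolates the data (noise-free panels) it is returned exactly
with zero variance components, and if every start fails the profile or
`nls` solution is returned flagged. The transect share of variance is
$\sigma_u^2 / (\sigma_u^2 + \sigma_\varepsilon^2)$.

The hockey-stick threshold is a continuous two-segment least-squares fit:
profile search on a 0.5 m breakpoint lattice (at least 3 points per side),
local refinement, ties broken toward the smaller breakpoint, and a
breakpoint is only "supported" when it improves the single-line SSE by at
least 1% — a pure line yields an explicit no-breakpoint flag. Edge
classification is half-open: distance < 40 m is edge, exactly 40 m is
interior.

# Phenology models

Stratum PAI is modelled with `nlme::lme`: categorical survey time, edge
class and (optionally) their interaction as fixed effects, random
intercepts for edge class nested within transect, and optionally a distinct
residual variance multiplier per edge class (varIdent). Candidate
fixed-effect structures (additive, full interaction, edge + interaction
without the time main effect) are fitted by ML so AICs are comparable —
REML is reserved for refitting a selected model for reporting — and
`select_model()` takes the lowest AIC, treating differences under 2 as ties
resolved toward the simplest structure. The interaction is tested with the
conditional F-test (containment denominator degrees of freedom). On
zero-residual data the mixed fit is degenerate and the exact OLS solution is
returned with variance components at zero.

## Permutation envelopes

Stability of coefficients and predicted time × edge cell means is assessed
by refitting on `n = 200` random calibration subsets holding 80% of each
transect × edge × time cell (stratified so no design cell is ever lost; a
resample that loses one is redrawn). Estimates from overlapping
80%-subsamples scatter about the full-data fit with roughly
$\sqrt{(1-s)/s} = 1/2$ of the full sampling standard error, so raw
2.5%/97.5% quantiles of the refit distribution would cover the truth far
below nominal. The default envelope therefore recentres the quantile
deviations on the full-data estimate and inflates them by the delete-d
jackknife factor $\sqrt{s/(1-s)} = 2$, which restores near-nominal (≈95%)
coverage for the within-dataset contrasts (time and interaction terms);
`scale = "raw"` reproduces the unscaled construction. Coverage is assessed
on the time-contrast coefficients because the intercept and edge main
effect are confounded with the realised transect intercepts of a given
layout — the envelope quantifies uncertainty conditional on the transect
layout, as any single-campaign analysis must.

## Strata coupling

Understory–canopy coupling is an ordinary least-squares regression of
per-survey mean understory PAI on per-survey mean upper-canopy PAI (one
point per survey), with an option to exclude a designated survey for
sensitivity. Observed survey-mean R² attenuates with column-sampling noise:
with only ~80 interior columns it drops to ~0.7 even when the underlying
trajectory coupling is 0.82, which is why the acceptance computation uses
panels matching the field sampling effort (~3000 interior columns per
stratum).

# Climate

Dry season is classified from the *trailing* 30-day rainfall sum (the
accumulation-up-to-date reading of a running monthly total): a date is dry
when the sum is under 200 mm, short wet interruptions can optionally be
bridged, and the first 29 dates are flagged partial rather than labelled.
Date gaps are an error — no silent interpolation. Microclimate loggers are
aggregated per logger-day to maximum air temperature and mean soil
moisture, with the expected readings per day inferred from each logger's
own cadence (so aggregating an already-daily series is the identity), a 75%
coverage flag, and a 35 °C heat-day threshold. The rainfall generator
produces gamma daily totals whose mean ramps between a wet regime
(~315 mm/30 d) and a four-month dry window (~96 mm/30 d, mid-June to
mid-October); the microclimate generator combines a Gaussian seasonal peak
(interior daily maxima crossing 35 °C only near the late-September peak), a
sinusoidal diurnal cycle peaking at 14:30, an edge offset ramping from
1.5 °C (wet) to 4 °C (dry season, inside the reported 3–5 °C band), and
soil moisture declining from 0.40 to 0.24 cm³ cm⁻³ through the window. A
time-domain-transmission-to-moisture calibration hook is deliberately not
modelled; series are accepted as volumetric moisture (identity
calibration), with the soil constants (50% clay, 25% sand, 25% silt,
1100 kg m⁻³) shipped only as configuration defaults.

# Numerical choices and degenerate inputs

* Traversal tie-breaks: half-open segments; starting points nudged 10⁻¹² m
  into the grid; rays missing the grid return empty traversals, not errors.
* $\hat\lambda = 0$ (sampled) when a voxel has entering weight but no
  interceptions; unsampled voxels are `NA` + flag.
* Accumulator inputs are validated (beam fractions in (0, 1], non-negative
  sufficient statistics, intercepted ≤ entering); returns beyond the
  traversed extent are counted and skipped, not fatal.
* Noise-free model fits short-circuit to exact linear algebra rather than
  asking an optimiser to find a zero-variance optimum.
* Sub-seeds for every stochastic stage are derived deterministically from
  one master seed (kept below 2³¹), so identical configurations reproduce
  byte-identical pulse sets, panels and pipeline artifacts.

# Problem sizes

Test-suite and acceptance-script simulations are sized for a single CPU:
8³–10³-voxel scenes with 10⁴–1.5×10⁵ pulses for estimator recovery (≥200
rays per voxel); 100-seed replicates for breakpoint, edge-model and
strata-boundary recovery; 500 simulations for the interaction-test level;
60 outer × 60 inner refits for envelope coverage; and survey simulations at
800–4000 mdeg angular resolution. The strata-boundary demonstration through
the full ray-traced chain uses a thinned stand (understory PAD
0.25 m² m⁻³) because at the field-strength understory (optical depth ≈ 4
to 15 m height) a desk-scale pulse budget leaves upper-canopy voxels too
occluded for stable per-voxel estimates — a pulse-budget limitation, not an
estimator defect; the field protocol's 276 scans per campaign exist
precisely to overcome it.

# Known limitations

No spatial autocorrelation between neighbouring columns in the mixed
models; no temporal autocorrelation structures; no finite-free-path bias
correction for the attenuation estimator; no leaf/wood separation and no
per-voxel or view-angle-dependent G; LAS/LAZ, NetCDF and GeoTIFF containers
are not read or written — the documented plain-text CSV dialects are the
interchange formats.
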