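---
title: "Land surface phenology from multi-index vegetation time series: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land surface phenology from multi-index vegetation time series: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lspheno)
```

## What the package does

`lspheno` extracts land surface phenology (LSP) — the calendar timing of
vegetation green-up and senescence — from multiband surface-reflectance
time series, and compares how three vegetation indices place those dates:

* **EVI**, the enhanced vegetation index,
  $\mathrm{EVI} = 2.5\,(\rho_{nir}-\rho_{red})/(\rho_{nir}+6\rho_{red}-7.5\rho_{blue}+1)$;
* **kNDVI**, the kernelized NDVI,
  $\mathrm{kNDVI} = \tanh\!\big(((\rho_{nir}-\rho_{red})/2\sigma)^2\big)$,
  which with the recommended length scale $\sigma = 0.5(\rho_{nir}+\rho_{red})$
  reduces to $\tanh(\mathrm{NDVI}^2)$;
* **PPI**, the plant phenology index,
  $\mathrm{PPI} = -K \ln\frac{M-\mathrm{DVI}}{M-\mathrm{DVI}_s}$ with
  $\mathrm{DVI} = \rho_{nir}-\rho_{red}$ — the inversion of a modified
  Beer's-law canopy model, near-linear in leaf area index (LAI) and robust
  to snow and soil background.

Every processing stage is exercised against synthetic scenes whose
phenological truth is known in closed form, so the pipeline is validated by
parameter recovery rather than by visual inspection.

## The processing chain

1. **QA filtering and compositing** (`composite_8day`). Daily index values
   flagged good are averaged over fixed 8-day windows anchored at DOY
   1, 9, ..., 361 (46 per year; the MODIS convention — the anchoring is a
   package choice, since several conventions coexist). A window's weight is
   the fraction of good days it contains. Leading gaps in the first year of
   a record are filled with the climatological mean of the same composite
   position over later years (`fill_leading_gap`), flagged as filled and
   given full weight.
2. **Rough fit** (`whants_fit`). A weighted harmonic (HANTS-style)
   regression with `n_harmonics = 3` terms, iterated `n_outer_iter = 3`
   times under the TIMESAT-style upper-envelope rule (`wtsm_update`):
   points below the current fit are down-weighted in proportion to their
   normalized negative residual, with a floor of 5% of the original
   weight, and weights are never increased. The rationale is physical:
   clouds and snow only depress vegetation indices, so the upper envelope
   of the series is closer to the true canopy signal. Both counts are
   configuration, not data-derived; three harmonics resolve one asymmetric
   season without chasing noise.
3. **Season division** (`divide_seasons`). One growing season per calendar
   year (the temperate single-peak regime; double cropping is out of
   scope). The season peak is the day of the rough-fit maximum inside the
   year, window ends are the rough-fit minima on either side (periodic
   extension, clipped to the year ±90 days). A rough-fit amplitude below
   `amplitude_floor` (default 0.02 index units) marks the pixel-year
   "no seasonality" and it is skipped downstream.
4. **Fine fit** (`beck_fit`). The Beck double logistic
   $$v(t) = mn + (mx-mn)\left[\sigma\!\big(r_{sp}(t-s)\big) +
   \sigma\!\big(-r_{au}(t-a)\big) - 1\right]$$
   is fitted by bounded Levenberg–Marquardt least squares (analytic
   Jacobian, `minpack.lm`), initialized from data percentiles and the
   rough curve's half-amplitude crossings, with bounds: `mn`/`mx` inside
   the data range ±0.2 amplitude, `s`/`a` inside the season window ±30
   days, rates in (0.001, 2]. One envelope reweight-and-refit cycle
   follows convergence. Non-convergence returns the best parameters with a
   flag; all fits are deterministic.
5. **Gu-method extraction** (`build_gu_lines`, `extract_gu_metrics`). On
   the reconstructed daily curve, the *recovery line* is the tangent at
   the maximum derivative before the peak, the *senescence line* the
   tangent at the minimum derivative after it (ties to the earliest day);
   *baseline* and *maxline* are the curve minimum and maximum in the
   window; the *plateau line* is an OLS fit of the curve between the
   stabilization and initial downturn dates. Five dates follow as analytic
   line intersections: UD (recovery×baseline), SD (recovery×maxline),
   DD0 (senescence×maxline), DD (senescence×plateau — the
   greendown-adjusted downturn), RD (senescence×baseline). Dates are
   real-valued days; rounding happens only at output.
6. **Consistency statistics** (`pearson_map`, `tower_window_mean`,
   `align_to_8day`, `cv_linear_regression`, `residual_seasonal_bins`).
   Per-pixel Pearson correlation against a reference cube (e.g. SIF);
   3×3-pixel footprint means for tower comparisons; daily reference series
   binned to the composite grid with an optional signed alignment shift;
   10-fold cross-validated simple regression reporting out-of-fold $R^2$,
   RMSE and the median bias $\mathrm{median}(y - \hat y)$ — negative bias
   means overestimation; residual summaries over the DOY bins [1,60),
   [60,150), [150,240), [240,330), [330,366).
7. **Trend analysis** (`theil_sen`, `mann_kendall`, `trend_map`,
   `region_summary`). Per-pixel Theil–Sen median slopes of annual metric
   series and the Mann–Kendall test with tie-corrected variance and
   continuity correction; significance classes use $|Z| \ge 1.96$ (95%)
   and $|Z| > 2.56$ (99%) — 2.56 rather than the conventional 2.576, kept
   as the field reports it. Regional trends average the annual series over
   the region first and then estimate the trend (the basin-mean
   treatment); pixel-level fractions (percent significant, percent of
   significant pixels advancing/delaying) are reported separately. No
   autocorrelation pre-whitening is applied; that is a documented
   limitation of the plain Mann–Kendall test.

## The closed-form oracle

For a pure Beck curve with well-separated seasons the tangent at the
spring inflection has slope $(mx-mn)\,r_{sp}/4$ through the half-amplitude
point, giving exactly

$$UD = s - 2/r_{sp},\quad SD = s + 2/r_{sp},\quad
DD0 = a - 2/r_{au},\quad RD = a + 2/r_{au},$$

with DD = DD0 when the plateau is flat (`gu_closed_form`). The numerical
extraction is tested to agree within one day over random parameter sweeps.
Two validity limits matter:

* *Separation*: the identities hold only when
  $a - s > 2/r_{sp} + 2/r_{au} + 10$ days; the oracle refuses otherwise.
* *Plateau shortfall*: the OLS plateau line sits slightly below the
  maxline (the curve dips by $\ln(1+e^{-2}) \approx 0.127$ amplitude units
  per unit rate at its ends), displacing DD behind DD0 by roughly
  $0.5(1/r_{sp}+1/r_{au})/(r_{au}\,(DD0-SD))$ days. For rates at or above
  0.12 day⁻¹ and generously separated seasons this stays below one day,
  which defines the sweep domain used in the equivalence tests; at
  shallower rates (e.g. 0.1 day⁻¹) the literal geometry trails the oracle
  by about a day. Whether the adjusted DD should precede or follow DD0
  under greendown is not settled in the literature; the geometric
  definition is implemented literally, and with a below-maxline plateau it
  places DD ≥ DD0.

## The synthetic-scene generator

`simulate_scene` produces daily 3-band reflectance on a 365-day calendar
from a per-pixel double-logistic LAI trajectory:

* **Truth** (`make_truth`): baseline LAI 0.2, peak 3.0 m²/m², spring
  inflection DOY 130 with rate 0.2 day⁻¹, autumn inflection DOY 285 with
  rate 0.15 day⁻¹; smooth spatial gradients (±5 days across the grid in
  the inflections, ±0.25 in peak LAI), interannual jitter of 2 days, and
  optional linear trends in days per year. Peak LAI 3 and the 0.5 m⁻²·m²
  LAI-to-DVI extinction are typical of the temperate grassland/forest
  mosaics this kind of analysis targets. The autumn rate 0.15 day⁻¹ was
  chosen so that the earliest structural transition (DD0, 2/0.15 ≈ 13
  days before the inflection) still falls inside the window in which the
  photosynthetic proxies have already begun declining (20-day lead, see
  below), mirroring the physiological ordering the generator is meant to
  emulate.
* **Optics** (`reflectance_from_lai`): Beer's law
  $\mathrm{DVI} = M - (M - \mathrm{DVI}_s)e^{-k\,\mathrm{LAI}}$ with
  $M = 0.7$, $\mathrm{DVI}_s = 0.09$, $k = 0.5$; red and blue sit on
  constant backgrounds (0.05, 0.03) and all bands receive independent
  Gaussian noise (sd 0.02 reflectance units by default). By construction,
  computing PPI with the generator's own $M$ and any constant $K$ returns
  $K\,k\,\mathrm{LAI}$ exactly — the linearity the index is designed for.
* **Contamination** (`contaminate`): cloud days (20% by default) depress
  the DVI by ≈0.15 on average and are QA-flagged with probability 0.9;
  the unflagged remainder is what the envelope weighting must absorb.
  Snow days inside the winter window push the visible bands toward 0.7
  and the DVI toward zero, occasionally escaping QA. Real archives come
  with no quantitative contamination model; all magnitudes are
  configuration with these documented defaults.
* **Fluxes** (`simulate_sif_gpp`): GPP is
  $\mathrm{lue}\,(1-e^{-0.5\,\mathrm{LAI}})\,S(t)$ — the saturating term
  is an fPAR proxy; any saturating monotone function would do — where the
  seasonal scalar $S(t)$ is 1 until 20 days (`autumn_lead_days`) before
  the structural autumn inflection and then declines logistically. SIF is
  proportional to GPP plus seeded noise. This reproduces, by design, the
  qualitative observation that photosynthesis declines before canopy
  structure does.

What the generator does *not* emulate: BRDF and solar-geometry effects on
reflectance, atmospheric variability, real land-cover heterogeneity,
multi-season (double-cropping) cycles, and spatially correlated weather.
Passing recovery tests on these scenes therefore demonstrates the
correctness and calibration of the algorithms, not performance on real
satellite archives.

## Numerical choices that required a decision

* **PPI clamp margin** (`eps = 0.01` DVI units). The observation nearest
  the record maximum necessarily approaches the log singularity at
  $\mathrm{DVI} = M$. A margin at the composite noise floor caps PPI at a
  finite, physically meaningful value; a much smaller margin would turn
  that observation into an extreme high outlier that upper-envelope
  weighting — which only down-weights *low* points — cannot suppress.
* **Canopy maximum $M$** (`M_margin = 0.15`). $M$ is estimated per pixel
  as the maximum of the daily good-QA DVI record, inflated by 15% of its
  dynamic range above bare soil:
  $M = \mathrm{DVI}_s + 1.15\,(\max \mathrm{DVI} - \mathrm{DVI}_s)$.
  The record maximum is a *lower bound* for the Beer's-law asymptote — it
  falls short by $e^{-k\,\mathrm{LAI}_{peak}}$ of the dynamic range, i.e.
  10–30% for peak LAI 2.5–4.5 — and using it directly over-sharpens the
  log transform near the seasonal peak, which we measured as a
  several-day early bias in the autumn dates. The 15% inflation
  compensates the middle of that range. A known asymptote can be supplied
  via `M_override` (e.g. for noise-free synthetic scenes, where the
  record maximum coincides with the seasonal plateau and the estimator
  degenerates).
* **Solar zenith for the PPI gain** (`theta_mode = "fixed"`). The gain
  $K(\theta)$ rescales PPI; with a constant $\theta$ it is a pure scale
  factor and the Gu dates are exactly invariant to it (metrics are
  invariant under affine transforms of the index axis). Evaluating
  $\theta$ per composite date instead makes $K$ seasonal, which is only
  correct when the reflectance itself carries the solar-geometry
  seasonality that $K$ is designed to normalize. The synthetic scenes
  deliberately carry none, and applying a seasonal $K$ to them imprints a
  spurious early autumn decline on PPI (we measured ≈11 days on DD0). The
  default is therefore one fixed angle — the equinox noon zenith at the
  scene latitude — with the per-date mode (`theta_mode = "noon"`)
  available for data with genuine solar-geometry seasonality.
* **Diffuse fraction** `dc = 0` (pure direct beam). No standard value is
  available for the diffuse fraction entering the gain; it is
  configuration, and with a fixed $\theta$ it only rescales PPI.
* **Bias convention**: `bias_median = median(observed − estimated)`, so
  systematic overestimation yields negative bias.
* **Cross-validation folds**: one seeded shuffle followed by a contiguous
  split into near-equal folds; fold construction is not standardized in
  the field and is recorded here.
* **Optimizer**: at most 200 Levenberg–Marquardt iterations per cycle,
  parameter tolerance 1e-8; season windows are half-open `[start,
  start+8)`; DOY is 1-based; grids are row-major with row 1 at the north.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script scenes are sized for a laptop-class
single core: a 20×20-pixel single-year scene for transition-date recovery
(1,200 pixel-season fits across three indices), a 10×10 scene over 24
years for trend recovery, a 16×16 (script) or 24×24 (tests) trendless
scene for false-positive calibration, 50 seeded draws for the
envelope-benefit comparison and 10,000 white-noise series for
Mann–Kendall calibration. These sizes give standard errors comfortably
inside the asserted tolerances; larger grids change nothing structurally.

## Known limitations

* Transition dates extracted from indices that are *nonlinear* in LAI
  (EVI, kNDVI, and DVI itself) are systematically displaced relative to
  the LAI-defined dates — on the default scenes by about −4 to −6 days in
  UD and +6 to +9 days in RD for EVI/kNDVI, with PPI within ±1 day. This
  is not an artifact of the fitting chain (direct tangent extraction on
  the analytic index curves shows the same offsets); it is the geometric
  consequence of index saturation, and precisely the reason a
  LAI-linear index places autumn transitions earlier than greenness
  indices do. Cross-index date comparisons should be read with this in
  mind.
* The Mann–Kendall test is applied without pre-whitening; serially
  correlated annual series will inflate its false-positive rate.
* One growing season per calendar year is assumed throughout.
* The QA flag is binary at the package boundary; bit-field QA products
  must be reduced to good/poor upstream.
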