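---
title: "Decomposing annual GPP variability into phenology and physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing annual GPP variability into phenology and physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smipp)
```

## The model

Annual gross primary productivity (GPP, g C m^-2^ yr^-1^) integrates a
seasonal curve of daily carbon uptake whose year-to-year variation can be
summarised by three indicators: the start of the growing season
(GS~start~, DOY), the seasonal maximum of daily GPP (GPP~max~,
g C m^-2^ d^-1^), and the end of the growing season (GS~end~, DOY).
GS~start~ and GS~end~ describe *phenology* — when uptake switches on and
off — while GPP~max~ describes *physiology*, the peak photosynthetic
capacity reached in summer.

Writing annual GPP as a function of the three indicators and taking its
total differential, the yearly anomaly of annual GPP (departure from the
record mean, ΔGPP) decomposes linearly:

ΔGPP ≈ η~start~·ΔGS~start~ + η~max~·ΔGPP~max~ + η~end~·ΔGS~end~

where the η are sensitivity coefficients — partial derivatives of annual
GPP with respect to each indicator — estimated per pixel or site by
ordinary least squares of ΔGPP on the three indicator anomalies
(`fit_smipp()`). Two sign conventions make the phenology coefficients
directly comparable: ΔGS~start~ is counted **positive when the start
advances** and ΔGS~end~ **positive when the end delays**, so that under a
"longer season means more uptake" regime both coefficients are expected
positive, in units of g C m^-2^ per day.

The decomposition assumes the three indicators vary (approximately)
independently; `check_independence()` reports the pairwise R² among the
predictors but, following standard practice for this model, no
collinearity correction is applied — the fit metadata simply carries the
report. The linearisation also assumes anomalies are small relative to the
curvature of the underlying response, which holds for the few-day,
few-percent year-to-year variation the model targets.

### Indicator extraction

Indicators are read off a *smoothed* daily curve, not the raw data:

* **8-day gridded composites** are fitted, per year, with a sixth-degree
  polynomial in DOY over the whole year (`fit_seasonal_polynomial()`).
* **Daily site series** are smoothed by singular spectrum analysis
  (`ssa_smooth()`): embed one year in an L × (365 − L + 1) Hankel
  trajectory matrix, take the SVD, and reconstruct from the four leading
  eigentriples by anti-diagonal averaging. Four components keep the
  lowest-frequency sub-signals (the seasonal shape) and discard weather
  noise.

GPP~max~ is the maximum of the smoothed curve (clamped at zero);
GS~start~/GS~end~ are the first/last whole days on which the clamped curve
is at or above a threshold equal to **10% of the long-term mean GPP~max~**
of that pixel or site (`compute_threshold()`, `extract_indicators()`).
Annual GPP is integrated from the *raw* series: the plain sum for daily
data, and Σ value~k~ × days~k~ for composites (8 days each, 5 for the
final composite of the 365-day year).

### Attribution

With the fitted components c~x,i~ = η~x~·Δx~i~ in hand:

* **Trend mode** (`trend_contributions()`): each component's OLS trend
  slope is expressed as a share of the total absolute slope of the three,
  in percent, signed positive only when the component trend agrees in sign
  with the annual-GPP trend. Absolute shares sum to 100 by construction.
* **Inter-annual variability (IAV) mode** (`iav_contributions()`): each
  component is credited by its *consistency* with the reconstructed annual
  anomaly Ĝ~i~ = Σ~x~ c~x,i~ : c_x-share = 100·Σ~i~ c~x,i~·sign(Ĝ~i~) /
  Σ~i~|Ĝ~i~|. Years in which a component moves with the total anomaly
  contribute positively, weighted by the year's anomaly magnitude, and
  the signed shares sum to exactly 100.

Referencing the IAV shares to the reconstructed anomaly (rather than the
observed ΔGPP) guarantees the exact 100% closure; the observed-anomaly
variant is available (`reference = "observed"`) and closes only
approximately, by the regression residual.

### Climate sensitivity

Phenology responds to the temperature immediately preceding the
transition, so each indicator is regressed on its own climate window
(`preseason_aggregate()`, `summer_aggregate()`, `sensitivity()`):

* GS~start~ and GS~end~: mean climate over the **30 days preceding the
  long-term mean date** of that indicator. Anchoring the window at the
  long-term mean date (not each year's own date) keeps the window fixed
  across years and avoids selection-induced correlation.
* GPP~max~: June–July–August means (DOY 152–243 of the 365-day calendar).
  For precipitation the JJA summary can be the mean *monthly* total
  (total ÷ 3), the conventional units for summer rainfall.

`sensitivity()` reports the Pearson correlation, the OLS slope with its
standard error, and a two-sided p-value. Indicators enter in raw calendar
units (larger GS~start~ = later start); the "days earlier per °C" reading
is a reporting convention, applied to |slope| only when summarising.
`partial_correlation()` residualises both series on two control climate
variables and correlates the residuals, with n − 4 degrees of freedom.

## The synthetic generator

No gridded GPP product or flux-tower archive ships with the package;
instead `simulate_site()` / `simulate_grid()` generate data with *known*
ground truth so every stage has a recovery test.

Each year's noise-free curve is a symmetric sine-power bump
(`seasonal_curve()`): GPP~max~·cos^2^(π(d − m)/(2H)) on a support of
half-width H around the season midpoint m, zero outside, with H solved
analytically so the curve crosses 10% of GPP~max~ *exactly* at GS~start~
and GS~end~. Threshold-crossing ground truth is therefore bit-defined
rather than itself estimated. Annual-GPP truth is the exact sum of the
noise-free daily curve.

Per year, each indicator truth is
mean + trend·(year index) + coupling·(temperature anomaly) + Gaussian IAV.
Daily temperature is a seasonal sinusoid plus a year-specific anomaly that
is constant within each of three seasonal blocks (DOY 1–151, 152–243,
244–365) and independent across blocks and years, plus day-to-day noise.
The three couplings are driven by the *realized* mean temperature of each
indicator's own aggregation window (the 30-day preseason for
GS~start~/GS~end~, JJA for GPP~max~), so regressing generated truths on
aggregated climate recovers the prescribed sensitivities without
errors-in-variables attenuation, and the block structure keeps the three
drivers mutually independent — mirroring the model's independence premise.

Defaults describe a mid-latitude temperate site: season DOY 120→280,
GPP~max~ 10 g C m^-2^ d^-1^, couplings −1.9 d °C^-1^ (start),
+1.7 d °C^-1^ (end) and +0.2 g C m^-2^ d^-1^ °C^-1^ (peak), seasonal
temperature-anomaly SD 2.0 °C, daily temperature noise SD 1.5 °C,
indicator IAV SDs 2.5 d / 2.5 d / 0.5 g C m^-2^ d^-1^, and additive
Gaussian observation noise (SD 0.5 g C m^-2^ d^-1^) clipped at zero —
values in the range routinely reported for temperate-zone interannual
phenology and flux variability. Precipitation (gamma daily totals) and
radiation (sinusoid + noise) are generated for interface completeness but
drive nothing.

What the generator does **not** emulate: spatial autocorrelation between
pixels, drought or disturbance events (noise is stationary Gaussian),
bimodal seasons, evergreen ecosystems whose curve never falls below the
threshold, gap structure typical of real flux records, or any
radiative-transfer/light-use-efficiency process. Passing recovery tests
therefore demonstrates the *estimators* are correct and calibrated on
data obeying the model's assumptions — not that real-world GPP obeys them.

```{r example}
site <- simulate_site(truth_params(seed = 42))
ind <- extract_phenology(site$gpp, cadence = "daily")
fit <- fit_smipp(build_anomalies(ind))
fit
iav_contributions(decompose_anomalies(fit))[c("c_start", "c_max", "c_end")]
```

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| threshold fraction | 0.10 | — | of the long-term mean GPP~max~ |
| polynomial degree | 6 | — | 8-day cadence smoother |
| SSA window L | 120 | days | ≥ one season, ≤ ~N/3 |
| SSA components | 4 | eigentriples | lowest-frequency sub-signals |
| preseason window | 30 | days | before the mean indicator date |
| minimum years | 5 | years | ≥ 1 residual df for 4 parameters |
| missing tolerance | 20% | per year | omission (polynomial) / interpolation (SSA) |
| IAV reference | reconstructed | — | exact closure; `"observed"` optional |

The SSA window is not dictated by the method; 120 days covers at least a
full season while staying under a third of the year, the standard SSA
trade-off. `n_components` counts eigentriples (not paired harmonics).

## Numerical choices

* The polynomial predictor is centred and scaled to [−1, 1]
  (x = (DOY − 183)/182) before forming powers: raw DOY^6^ ≈ 2×10^15^
  destroys the conditioning of the normal equations. Coefficients are
  stored in the scaled basis with the transform recorded, and curves are
  evaluated by Horner's scheme.
* 8-day composites take their first day + 3.5 as regression abscissa.
* Negative smoothed values are kept in the stored curve and clamped to
  zero only at indicator extraction, preventing spurious threshold
  crossings without distorting the fit.
* Crossings are whole days (first day at-or-above), with no sub-daily
  interpolation: indicators are reported as whole DOYs and interpolation
  precision is below indicator noise. Ties at the maximum break to the
  earliest day. For bimodal curves the first rising and last falling
  crossings of the whole year are used.
* Peak search on polynomial curves is restricted to DOY 15–350 because
  degree-6 fits can diverge at the year edges; years whose peak falls
  outside [GS~start~, GS~end~], or that never reach the threshold (e.g.
  evergreen-like curves), are flagged invalid rather than filled, and are
  excluded listwise from the regression.
* The SMIPP regression keeps an intercept even though mean-centred
  anomalies force it to ≈ 0: it preserves the exact reconstruction
  identity when years are dropped after centring. A no-intercept variant
  is available.
* Winter composites are used as-is (no zero-filling) in the whole-year
  polynomial fit; missing-data handling is config, defaulting to 20%
  tolerance.
* The 365-day calendar drops Feb 29 everywhere, matching the 46 × 8-day
  composite year; file readers renumber post-leap days accordingly.

## Validation design and problem sizes

The test suite validates each stage against independent brute-force
oracles (naive polynomial evaluation, closed-form OLS moments,
residual-regression partial correlation, literal share formulas, direct
8-day slicing) on batches of ≥ 100 random instances, plus property checks:
exact recovery of noise-free anomaly tables (tolerance 1e−8), exact
100-closure of both contribution modes over 1,000 random instances
(1e−9), ±1-day / 1% indicator recovery on 200 noise-free pixels drawn from
the generator's truth distribution, and determinism of the full pipeline
on a seeded 4×4 grid via an FNV-1a manifest hash.

Two ensemble experiments quantify estimator calibration at desk scale:

* `recover_smipp_coefficients()`: 500 cells × 15 years with generating
  coefficients (2.9, 95.9, 2.4) and noise set analytically from the
  target per-cell R² of 0.98 (noise variance = signal variance ×
  (1 − R²)/R²; anomaly SDs 4 d, 0.8 g C m^-2^ d^-1^, 4 d). Ensemble-mean
  coefficients are compared with truth at 2 Monte-Carlo SEs.
* `recover_climate_sensitivity()`: 20 sites × 15 years (300 site-years)
  with couplings −1.9/+1.7 d °C^-1^; per-site preseason aggregation and
  OLS, then the mean absolute slope. The regression uses the generated
  indicator values, isolating the climate-sensitivity operations; the
  `source = "extracted"` variant runs SSA + threshold extraction first
  and carries the extraction estimator's additional noise. The
  Monte-Carlo SE of the ensemble mean pools the per-site regression SEs
  (~240 residual df) rather than the 19-df across-site SD — the same
  estimand, estimated far more stably.

These sizes keep the whole suite in tens of seconds on one CPU while
leaving Monte-Carlo SEs well below the effects being recovered.

## Known limitations

* SSA with four components and L = 120 blurs seasons narrower than about
  135 days; threshold crossings can then miss by ~2 days even without
  noise. Boreal short-season applications should raise `n_components`
  or shorten the window.
* Under observation noise, the clip-at-zero floor slightly raises the
  smoothed off-season tail, shifting both crossings outward by a fraction
  of a day and attenuating extracted-indicator climate slopes by a few
  percent — visible with `source = "extracted"` in the recovery
  experiment.
* Polynomial smoothing of 8-day data resolves peaks to ~5% and peak
  timing to ~1 week; it is a coarser instrument than daily SSA, as its
  acceptance tolerances reflect.
* Per-pixel regressions are fitted independently: no spatial pooling, no
  autocorrelation correction in trend p-values (15 annual points), and
  unadjusted per-pixel p-values — significance masking across maps is a
  rendering decision, not performed here.
* Gridded products are exchanged as long-format CSV; the grid writer
  targets portability of the validation pipeline, not archival storage of
  large rasters.
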