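---
title: "Methods: linking regional climate variability to wine composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking regional climate variability to wine composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinoclim)
```

## The scientific problem

Wine regions with a Mediterranean-continental climate — hot, dry summers,
spring and autumn precipitation maxima, around 405 mm of rain a year —
are sensitive recorders of climate variability. Inter-annual swings in
heat accumulation and water balance shift must chemistry (sugar-derived
probable alcohol, pH, tartaric acidity), berry size, and the timing of
veraison and harvest; satellite leaf-area index (LAI) registers the same
signal in canopy density; and the regional weather anomalies themselves
are organised by North Atlantic teleconnection modes and, more remotely,
by tropical Pacific sea-surface temperature (SST).

`vinoclim` implements the full analysis chain that connects these layers:

1. **Bioclimatic indices** from daily station data (`bioclim_table()`).
2. **Mean-centered PCA** of the annual vintage table (`run_pca()`), the
   leading score being a "hot vintage" index.
3. **Nonparametric statistics** — Mann-Kendall/Theil-Sen trends, partial
   correlation with calendar year as the control, Kruskal-Wallis with
   Conover-Iman follow-up — implemented from scratch
   (`mann_kendall()` and friends).
4. **Tercile composites** of monthly anomalies over extreme-index years
   with bootstrap significance envelopes (`composite_report()`).
5. **Gridded operations**: vineyard-pixel selection, regional LAI
   series, seasonal SST means and correlation maps with analytic
   significance masks (`correlation_map()`).

Because real vintage records of this kind are typically confidential,
the package ships a synthetic-data module whose couplings are known
exactly, so every stage has a parameter-recovery test surface. The
generators are first-class, tested code, not fixtures.

## The synthetic-data generators

The generators define the study conditions used throughout the test
suite; their defaults were chosen once, from regional climatology, and
are not tuned per test.

**Daily weather** (`generate_daily_weather()`). Temperature is a cosine
seasonal cycle peaking in late July plus a shared AR(1) anomaly
(coefficient 0.7, innovation sd 2 °C) — TX and TN move together, with
independent noise on the diurnal range and TN clamped below TX. A
linear warming trend (default 0.4 °C/decade, the order observed in the
Ebro valley in recent decades) is applied to both. Precipitation uses a
two-state Markov occurrence chain (p(wet|wet) = 0.45, p(wet|dry) = 0.22)
with monthly multipliers producing spring and autumn maxima, and
gamma-distributed wet-day amounts. The gamma scale was set analytically
(stationary wet fraction × mean amount × 365.25) so the expected annual
total is 405 mm, the regional climatological value. Sunshine, cloud
cover and humidity are linear responses to the temperature anomaly and
the wet/dry state, clipped to physical ranges. The model is
deliberately the simplest structure with controllable persistence; it
does not reproduce spells of blocking weather, convective extremes, or
spatial coherence, so passing tests say nothing about those features of
real data.

**Vintage table** (`generate_wine_table()`). Each variable is a linear
function of four standardized drivers — May, June, July TX anomalies
and an April–September water balance (precipitation minus Thornthwaite
PET) — plus Gaussian noise. Default signs encode the expected
physiology: alcohol and pH rise with heat, acidity and the phenological
dates fall, berry weight rises with wetness, production and yield are
left uncoupled (management-driven in practice). The ground-truth slope
matrix is attached to the returned table. Linearity is a modelling
convenience that makes partial-correlation and composite recovery
analytically predictable; real responses saturate and interact.

**LAI grid** (`generate_lai_grid()`). The annual cycle is a
double-logistic curve (green-up centred in April, senescence in
October, dormant-season floor 0.3 m²/m², peak 2.2 m²/m²); summer months
receive `coupling × z(summer TX)`, default −0.3, reproducing the
heat-reduces-canopy signal. A vineyard-fraction table accompanies the
grid for the ≥ 0.75 selection rule.

**Teleconnections** (`generate_teleconnection_indices()`). Four
standardized AR(1) monthly series (NAO, EA, EA/WR, SCAND; coefficient
0.3). An optional coupling replaces May EA with
`c·z(May TX) + sqrt(1−c²)·EA`, imposing a known May correlation.

**SST** (`generate_sst_field()`). A fixed dipole of two opposite-signed
Gaussian lobes in a tropical band (an idealised ENSO-like mode) scales
an annual driver; December is attributed to the following year so the
previous-December-to-May window mean is exact. The pattern is stored
with the field for recovery tests.

## Bioclimatic indices: conventions and numerical choices

- **Tmean = (TX + TN)/2** throughout, the convention of the index
  literature.
- **Day counts** use strict inequalities: hot days TX > 30 °C, frost
  days TN < 0 °C, wet days PP > 1 mm. A day at exactly the threshold
  does not count.
- **Growing Degree Days**: Σ max(0, Tmean − 10 °C), April–October.
- **Huglin heliothermal index**: Σ K·max(0, ((Tmean−10)+(TX−10))/2),
  April–September. The day-length coefficient K uses a stepwise table
  (1.02/1.03/1.04/1.05/1.06 at 40/42/44/46/48–50°) with linear
  interpolation, flat below 40° and an error above 50° (outside the
  published table). At 42.45°N, K ≈ 1.03.
- **Cool Night Index**: mean September TN.
- **Dryness Index**: monthly balance W ← min(200, W + P − Tv − Es) over
  April–September from an initial 200 mm reserve, with Tv = k·PET,
  Es = (PET/N)(1−k)·JPm, k = 0.1/0.3/0.5 (Apr/May/Jun–Sep), and
  JPm = min(N/5, wet-day count) — the wet-day proxy is an approximation
  to the published formulation. W may go negative, as the index's class
  limits require. PET defaults to Thornthwaite (it needs only monthly
  Tmean and latitude); the `pet` argument accepts any substitute such
  as Hargreaves.
- **Drought index windows**: the consumed monthly drought index is
  summarised as means over July–September, March–September, and October
  (previous year)–September. Note the growing-season window spans seven
  months despite the conventional "6-month" label; the implementation
  exposes the month lists explicitly.

## PCA of the vintage table

Variables mix units (% vol, g/L, grams, day-of-year), so the default
scaling is **center + standardize** (correlation matrix); plain
centering is available via `scaling = "center"` for unit-comparable
subsets. Components come from an eigendecomposition of the resulting
matrix, ordered by eigenvalue. Two deterministic sign rules remove the
eigenvector sign ambiguity: the largest-magnitude loading of each
component is made positive, and PC1 is additionally flipped, if needed,
so probable alcohol loads positively — positive PC1 then reads as
hot-vintage years. Rows with missing values are dropped listwise with a
logged count. Rank deficiency warns rather than fails; requesting more
components than the rank is an error.

## Nonparametric statistics

All five procedures are implemented directly (and cross-checked in the
tests against independent brute-force oracles and, where one exists, a
reference implementation):

- **Mann-Kendall** with the tie-corrected variance and a ±1 continuity
  correction on the normal deviate — accurate for series of ~25 years;
  the exact permutation null and autocorrelation-corrected
  (pre-whitened) variants are out of scope.
- **Theil-Sen**: median of pairwise slopes, duplicate time values
  excluded; the 95% interval is the classical rank-based one on the
  ordered slopes.
- **Partial correlation** by the first-order formula, p-value from the
  t distribution on n − 3 degrees of freedom; a control collinear with
  either variable is a degenerate-control error.
- **Kruskal-Wallis** on mid-ranks with the tie correction.
- **Conover-Iman** pairwise statistics on rank means with the pooled
  rank variance; raw p-values are reported alongside Holm-adjusted ones
  (the adjustment choice is ours — multiple-testing treatment is rarely
  stated in applied work of this kind, so both are exposed).
- **critical_r(n, α)** = t*/√(n−2+t*²) gives the analytic mask for
  correlation maps; at n = 25 it is 0.396, i.e. the familiar ±0.40.

## The composite procedure

`composite_report()` chains four steps, each exposed separately:

1. **Per-calendar-month detrending.** Each month's multi-year series is
   detrended by its own OLS line in year; the residual is original
   minus fitted trend. This reading (rather than one annual trend, or
   residual = original minus a smoothed series) makes the procedure
   exactly invariant to any linear-in-year trend in the input, which
   the tests verify.
2. **Tercile classification** of the annual index (itself linearly
   detrended by default): the floor(n/3) smallest and largest detrended
   values form the low and high sets — 8 years each for n = 25. Ties
   straddling a boundary are broken by year order (the earlier year
   enters the extreme set), deterministically.
3. **Composite anomalies**: plain means of the residuals over each
   extreme set, per calendar month.
4. **Bootstrap envelope**: 10,000 samples of m years, each averaged per
   month; the 5th and 95th percentiles of the replicate means bound the
   composite. One set of year draws per replicate is reused across all
   months, preserving cross-month dependence. A composite outside the
   envelope is flagged significant.

**With replacement or without?** The default draws years with
replacement (the classical bootstrap). But a tercile category is a
fixed-size subset drawn *without* replacement, whose mean has variance
smaller by the finite-population factor (n−m)/n· n/(n−1); against a
with-replacement envelope, null tercile composites therefore breach the
5–95% band in roughly 5–6% of cases rather than 10%. The
`replace = FALSE` subsampling variant is the calibrated null for
fixed-size categories, and the calibration tests use each variant
against its matching null: with-replacement draws breach the default
envelope at ≈ 10%, and tercile-style subsets breach the subsampling
envelope at ≈ 10%. Both variants give essentially identical power
(≥ 90% at a +1.5 sd May anomaly tied to the high-index years, the
package's reference detection scenario).

## Gridded operations

- `pixel_area()` uses a spherical Earth (R = 6371 km):
  (res·πR/180)²·cos φ. At the native 0.0727273° resolution this is
  48.3 km² at 42.45°N. (Note 0.75 × 48.3 ≈ 36 km², not the "around
  42 km²" sometimes quoted for 75% coverage; the fraction rule, not an
  area figure, is what the selection implements.)
- `select_vineyard_pixels()` keeps fraction ≥ 0.75 — "a minimum of 75%"
  is read as inclusive, and the boundary is tested.
- The regional LAI series is an **unweighted** mean over selected
  pixels: at a single latitude band pixels are near-equal in area.
  Area weights can be passed explicitly.
- `seasonal_sst_mean()` averages December of year t−1 through May of
  year t; years lacking the previous December are dropped.
- `correlation_map()` detrends both the index and each pixel series
  (flag-controlled), uses pairwise-complete samples, and masks at the
  per-pixel `critical_r(n)` — so pixels with missing years get the
  appropriately larger threshold.
- Conventions: pixel-center coordinates, north-positive latitude,
  longitude in [−180, 180), months 1–12, all month intervals inclusive.

## Problem sizes and reproducibility

The reference configuration throughout is a 25-year record (1993–2017),
the envelope uses 10,000 bootstrap draws, and the Monte-Carlo recovery
checks use 100–200 seeded replicates with reduced (2,000-draw)
envelopes, sizes at which every recovery rate sits far from its bound.
Every generator and every resampling routine takes an explicit integer
seed and is bit-reproducible; `run_report()` derives all stage seeds
from one master seed and records it in its manifest.

## Known limitations

- The weather generator has no spatial structure, no weather-type
  regimes and no extreme-event physics; the vintage response is linear
  and additive. Recovery of the injected couplings demonstrates the
  statistical machinery, not the realism of the couplings.
- The drought index is consumed, never fitted; the bundled proxy is a
  per-month standardized water balance, not the multi-scalar product.
- The Mann-Kendall implementation assumes serially independent
  residuals; with the generator's AR(1) daily persistence, monthly and
  annual aggregates are close to independent, but strongly
  autocorrelated user data would need pre-whitening the package does
  not provide.
- Composite significance is reported per month without field-wise
  (multiplicity) control, matching standard practice for this kind of
  annual-cycle display.
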