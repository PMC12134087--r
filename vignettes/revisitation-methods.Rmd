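---
title: "Methods: detecting and modelling foraging-site revisitation"
author: "revisit package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and modelling foraging-site revisitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model behind
each stage, the parameters that matter, the numerical conventions, what the
synthetic-study generator does and does not emulate, and the design choices
made where the design was genuinely open.

## The analysis in one paragraph

Large herbivores return to profitable foraging sites. Given hourly GPS
fixes of individual animals in a projected (metre) coordinate system, the
package (1) counts *revisits*: the number of separate time intervals a
track spends inside a circle centred on each fix, with a minimum time away
separating visits; (2) asks whether revisited sites are a non-random draw
from the accessible landscape, by comparing covariate distributions at
revisited sites against points sampled uniformly inside an a-LoCoH home
range (with water buffered out) using repeated small-sample Kolmogorov
tests; and (3) models the *revisitation rate* — visits per seasonal period
— as a log-linear function of environmental covariates with individual
random intercepts, selected backwards by AIC under a 2-ΔAIC parsimony
rule, with Nakagawa–Schielzeth R².

## Visit detection and the recursion table

A visit to the circle of radius $r$ at centre $c$ is a maximal interval the
interpolated track spends inside the closed disc. Entry and exit times
solve $|p_0 + s\,(p_1 - p_0) - c|^2 = r^2$ on each segment (constant
velocity between fixes), so times are linear interpolations, exact for the
polyline model. Conventions, chosen to be deterministic and testable:
fixes on the boundary count as inside; tangential (zero-discriminant)
contact is not a crossing; a track that starts or ends inside opens or
closes its visit at the first or last fix. Two consecutive in-circle
intervals merge when the gap between them is *strictly shorter* than the
minimum time away (default 12 h), so an absence of at least the threshold
starts a new visit. The recursion table puts one candidate site at every
fix of every individual — sites are deliberately not deduplicated across
overlapping circles, matching the moving-circle procedure. The core is
implemented in C++ because the table is quadratic in track length; the
single-centre R path and the C++ table are tested against each other and
against a brute-force oracle that resamples each segment at 1-second steps.

The circle radius is chosen by the variance-peak rule over candidate radii
(default 100–500 m): too small a circle gives uniformly low counts, too
large a circle homogenises them; the informative radius maximises the
across-site variance of visit counts. The variance is computed per
individual and summarised across individuals by the median — a robust
aggregation of a per-individual criterion; the aggregation rule is a
package decision, exposed as code, since only the per-individual behaviour
is conventionally described. Ties break to the smaller radius.

## Water, home range and availability

Sites within 500 m of permanent water are removed before analysis:
water-bound returns reflect drinking, not foraging. Distances are planar
Euclidean against point, line and polygon features (points inside a
polygon are at distance zero).

The availability model is complete spatial randomness inside an a-LoCoH
home range at isopleth 1 with the buffered water excluded. For each root
point the local set collects neighbours in order of increasing distance
while they stay within the adaptive radius $a$; local convex hulls are
unioned in ascending area order until the isopleth fraction of points is
covered. With the default $a$ — the maximum observed pairwise distance —
every local set is the full point set and the isopleth-1 range *is* the
global convex hull; the test suite asserts this collapse exactly. Smaller,
informative values of $a$ are supported, in which case the union is kept
as its member hulls (membership = inside any hull) and the area of a
non-collapsed union is reported as a fine-grid estimate, flagged as such.
The pooled (all-individual) range is used, thinned deterministically to at
most `homeRangeMaxPoints` (default 1500) fixes before the $O(n^2)$ hull
construction; with the default $a$ the thinning only trims the interior
point cloud, and the convex hull it produces is driven by the extremes.

Availability points are rejection-sampled uniformly in the range, must lie
strictly farther than the buffer from water, and are stamped with entry
times drawn with replacement from the observed visit entry times (needed
to extract dynamic covariates for random points; replacement because the
default 100,000 points exceed the number of observed entries).

## Covariates, transforms, seasons

Static rasters (phosphorus ppm, nitrogen g/kg, elevation m) are extracted
at the site centre by nearest cell, no interpolation and no circle
averaging — extraction is at the fix that defines the circle. Dynamic
series (EVI 16-day, day land-surface temperature 8-day, precipitation
5-day) use the last record at or before the relevant entry time; a record
exactly at the entry time counts, and the extraction can never look into
the future. Queries before the first record are missing, and missingness
flags rows rather than dropping them silently. Rasters are read and
written as ESRI ASCII grids (a plain-text single-band format) with a
`timestamp,path` index CSV per series; water features as GeoJSON.

Transforms: distance to water is square-root transformed (available area
grows quadratically with distance, so the transform linearises
availability); slope in degrees comes from Horn's 3×3 finite-difference
gradient on the elevation grid (border cells use edge replication and are
flagged) and is `log1p`-transformed — `log1p`, not `log`, because flat
terrain (0°) occurs and must stay finite while preserving log-scale
compression of the skewed slope distribution.

Seasons come from a domain-averaged NDVI series standardized over the
whole tracking period (sample-SD convention). Within each July–June
season-year — aligned so a southern-hemisphere November–April wet season
is never split — the smoothed series (centred moving mean, window 3
records) is thresholded at $z = 0$; the longest above-threshold run is the
wet season and its interpolated zero crossings are the year's two cut
points. The exact segmentation rule of the external tooling conventionally
used for this step is not published; the rule here is the simplest
two-cut-point scheme consistent with one wet season per year, and window,
threshold behaviour and fallbacks are all configurable. A year with no
usable crossing structure — no crossing, a longest run under 100 days, or
more than 4 sign flips (noise, not seasonality) — falls back with a
warning to the calendar default, wet November through April. Wet intervals
are closed: a timestamp exactly at a cut point is wet.

The collinearity screen computes pairwise Pearson correlations on complete
rows and drops, for any pair with $|r| > 0.5$ (strictly), the
lower-priority column; phosphorus has priority over nitrogen on ecological
grounds (phosphorus-driven forage selection), so the correlated nitrogen
field leaves the candidate set. A pair at exactly 0.5 is kept; constant
columns are flagged, never silently dropped.

## Rates and models

The revisitation rate of a site in a season type is the number of visits
whose entry falls in that type divided by the number of seasonal periods
of that type the individual's tracking span overlaps — fractional periods
counted fractionally, where a dry season runs from one wet season's end to
the next wet season's start (straddling the season-year boundary) and
truncated boundary periods count as fractions of a full season. Sites with
no visits in a season type contribute no record. The response is the log
rate: the lognormal is checked against normal, Weibull and gamma by
maximum-likelihood AIC (delegated to `fitdistrplus`), and the log-scale
response follows that choice.

Exploratory per-variable regressions first flatten the data imbalance:
the covariate range is cut into 1000 equal bins, the mean log rate per
non-empty bin is the regression point, and OLS on centre and centre² gives
the curvature. Precipitation participates here but is excluded from the
mixed models, where its effect is redundant with vegetation greenness.

The mixed model is log rate on scaled covariates (zero mean, unit SD
within the modelled subset; quadratics are built *after* scaling) with a
random intercept per individual, fitted by ML during selection so AICs are
comparable across fixed structures (`lme4`), and refit by REML for the
reported variance components. Backward selection removes the single
removable term whose removal lowers AIC most, respecting marginality
(quadratics before their linear terms, interactions before their main
effects), and stops when no removal lowers AIC; among all visited models
within 2 ΔAIC of the best, the one with fewest terms is chosen
(deterministic lexicographic tie-breaks). Models are fitted per sex ×
season stratum; selection operates on a stratified resample (10
equal-width strata per focal covariate, 50 rows per non-empty stratum,
union deduplicated) so heavily populated intermediate covariate values do
not dominate, and the chosen model's marginal and conditional R²
($R_m^2 = \sigma_f^2 / (\sigma_f^2 + \sigma_\alpha^2 + \sigma_\epsilon^2)$,
$R_c^2$ adds $\sigma_\alpha^2$ to the numerator) are averaged over
repeated stratified resamples (mean ± SD; 200 resamples by default, a
size at which the mean is stable to the second decimal). Interactions are
then added from an ecologically motivated allow-list — EVI×slope,
water×slope, EVI×phosphorus, water×phosphorus — restricted to variables
whose main effects survived base selection, and selection is re-run; an
empty allow-list returns the base selection unchanged. The exact
stratified-resampling recipe and the "visited models" universe for the
2-ΔAIC rule (path-visited models, not an exhaustive neighbourhood) are
declared package decisions, both configurable.

## The synthetic study

No field data ship with the package, so a seeded generator produces a
complete study whose truth is known. Covariate fields are
Gaussian-smoothed white noise (smoothing length 500 m on a 100 m grid);
nitrogen is $\rho\,z(P) + \sqrt{1-\rho^2}\,$ (independent field) with
$\rho = 0.8$; EVI/NDVI ride a seasonal sinusoid peaking mid-January;
temperature peaks in October — offset from greenness both for realism
(dry-season heat) and so the two fields are not collinear at the 0.5
screen threshold; precipitation is a seasonal sinusoid with multiplicative
noise. Water is a wandering river polyline plus Poisson waterholes.

Hotspots are cells sampled with probability $\propto e^\eta$ where
$\eta = \beta_1 z(P) + \beta_2 z(P)^2 + \beta_3 z(\sqrt{d_w}) +
\beta_4 z(\sqrt{d_w})^2$ — the planted effects live on the *transformed*
covariates so generator truth and modelling columns share one scale. The
defaults plant concave (hump-shaped) phosphorus and distance-to-water
effects ($\beta = 1, -1, 0.8, -0.8$). Movement alternates weighted-target
trips (biased correlated random walk: gamma step lengths, heading mixed
between persistence and bearing-to-target) with dwells that wander within
300 m of the hotspot centre, plus occasional >12 h excursion loops to
400–800 m. The loop design is what pins the variance peak to the planted
~250 m scale: 100 m circles miss part of the dwell wander, 200–300 m
circles resolve each loop as a separate revisit, and 400–500 m circles —
which the wandering animal never cleanly leaves for 12 h — absorb them.
Targets are drawn independently in proportion to hotspot weight, so
long-run visit counts track the planted weights; consecutive stays at the
same hotspot merge into one visit unless a loop splits them, which
compresses realised count ratios somewhat below the weight ratios.

What the generator does *not* emulate: behavioural memory decay, social
dynamics, sex-specific movement rules, fix dropout and location error,
cloud-contaminated imagery, or multi-modal (two-wet-season) years. Nor is
the realised rate distribution tuned to any particular family — the
trip/dwell mechanics happen to produce Weibull-like rates, so the
response-family step is validated by recovery simulations on draws from
known families, not by the synthetic study. Passing
tests therefore demonstrate that the pipeline recovers planted structure
under clean, stationary conditions — not that it is robust to every
artefact of real collar data.

Generator defaults describe the full study design (41 individuals — 29
bulls and 12 cows — hourly fixes, multi-year spans). Validation runs use a
reduced study of 5 individuals × 1 year (≈44,000 fixes, ≈44,000 candidate
sites), 20,000 availability points and 200 R² resamples; these problem
sizes are stated here as the package's validation design. Every stochastic
stage derives its stream from one master seed, and a rerun with the same
configuration reproduces reports bit-for-bit (numeric tables to 1e-12).

## Numerical conventions and edge cases

* Closed-disc membership; strict-inequality merging (`gap < minTimeAway`).
* Radius-selection ties go to the smaller radius; AIC/term-count ties in
  selection break lexicographically on the sorted term set.
* `binMeans` uses equal-width bins over the observed range, right-closed
  final bin, empty bins omitted; a constant covariate is an error.
* The Kolmogorov statistic is evaluated at all pooled jump points (ties
  exact); p-values use the asymptotic Kolmogorov distribution at
  $\lambda = \sqrt{n_e}\,D$, $n_e = mn/(m+n)$. On 100-vs-100 subsamples D
  is discrete (multiples of 1/100), so any p-value has atoms of mass
  ~0.1: calibration is checked against the exact discrete null
  (`stats::psmirnov`) rather than against a continuous uniform, which a
  discrete statistic can never match at large iteration counts.
* For a 3-SD location shift the exact separation oracle is
  $\sup_x |\Phi(x) - \Phi(x-3)| = 2\Phi(1.5) - 1 \approx 0.866$;
  subsampled means sit slightly above it.
* Normal data with mean 10 and unit SD are nearly indistinguishable from a
  high-shape gamma at $n = 1000$; family recovery for the normal case
  operates close to its identifiability limit (~90% win rate), unlike the
  other three families.
* Geographic-looking coordinates (|x| ≤ 360, |y| ≤ 90) are rejected at
  read time rather than silently reprojected; all analysis distances are
  planar metres.
* Degenerate geometry (collinear points, empty sampling regions,
  constant NDVI) errors early with a named cause; empty water sets warn
  and keep all sites.

## Known limitations

* The union area of a non-collapsed a-LoCoH range is a grid estimate
  (flagged); only the default parameterisation guarantees an exact area.
* Rasters must share one CRS and grid; no reprojection or resampling.
* No fix screening (HDOP, speed) is applied before analysis, and no
  multiple-testing adjustment is made across the per-variable Kolmogorov
  comparisons — both matching the analysis design this package
  implements.
* Random slopes, spatial autocorrelation structures and cross-validation
  are out of scope.
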