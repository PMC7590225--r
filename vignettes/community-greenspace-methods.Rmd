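---
title: "Measuring community green space under alternative spatial boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring community green space under alternative spatial boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(communitygreen)
```

## The problem

Ecological studies that relate green space to health must first decide *where*
a community's green space is. That decision is not innocent: results change
with the zoning scheme and the spatial scale used to build areal variables
(the modifiable areal unit problem, MAUP) and with how the contextual area of
daily activity is delineated (the uncertain geographic context problem,
UGCoP). This package implements a county-level sensitivity analysis around
those choices: six alternative delineations of "community activity space",
two seasonal greenness metrics, four buffer distances, and the statistical
battery that compares them — plus a synthetic-geography generator with
planted ground truth so that every stage is testable without any downloaded
census or satellite data.

## Boundary schemes

For each county the exposure zone is one of:

* **county** — the whole administrative unit;
* **h1ha / h10ha** — the dissolved union of block groups whose residential
  density is at least 1 household per hectare, respectively 1 household per
  10 hectares. Density is `households / area_ha`; if a stored area disagrees
  with the geometric area by more than 1% the geometry wins, and records with
  non-positive area are rejected with a diagnostic. The two thresholds nest,
  so the 1 H/1 HA zone is always a geometric subset of the 1 H/10 HAs zone;
* **place** — census-place polygons clipped to the county;
* **urban_area** — census urban-area polygons clipped to the county; counties
  without any urban area get an *empty* zone, a missing exposure value, and
  are dropped listwise from models under that scheme only;
* **combined** — the geometric union of place and urban area, the candidate
  operationalization of community activity space.

Each zone can be buffered by 0, 300, 500 or 1000 m (Euclidean, arcs
discretized at 16 segments per quarter circle, which keeps the area of a
buffered square within 0.2% of the closed form a² + 4ab + πb²). Zones are
clipped to their county *before* buffering; a buffer may then cross county
lines but its greenness is still attributed to the owning county — the
alternative (re-clipping after buffering) would make the 0 m and buffered
variants structurally different objects.

## Greenness metrics

Input is an annual stack of NDVI percent values (0–100) on a fixed planar
grid, nominally 250 m pixels, with at least four periods per year (default
12). Two per-pixel summaries are computed:

* **MXN**, the annual maximum of the series — the peak vegetation level;
* **TIN**, the time-integrated NDVI — average greenness over the growing
  season. The package defines it operationally: smooth the cycle with a
  3-period circular moving **median**; take `baseline` = smoothed minimum and
  `amplitude` = smoothed maximum − baseline; the growing season is the
  longest contiguous (circularly wrapped) run of periods whose smoothed value
  reaches `baseline + 0.10 · amplitude`, ties broken toward the earliest run;
  TIN is the mean of (raw − baseline) over that run, floored at zero. A flat
  series has zero amplitude, an empty season and TIN 0.

The 3-period window and the 10% threshold are arguments, not constants. The
median (rather than a moving mean) was chosen because it preserves abrupt
green-up edges: for an idealized half-year step from 20 to 70, a mean
smoother bleeds the step into adjacent periods, pulls them over the 10%
threshold and drags the seasonal average down to ≈ 43, whereas the median
keeps the season exactly at the plateau and yields the closed-form TIN of 50.
TIN is defined as a seasonal *average*, not an accumulated sum, so both
metrics live on the same 0–100 scale, and 0 ≤ TIN ≤ MXN ≤ 100 holds for
every pixel. MXN is invariant to period permutation; TIN is invariant to
circular rotation of the cycle and unchanged when a constant is added to all
periods (the baseline shifts equally).

Zonal extraction uses a pixel-center rule: a pixel contributes to a zone iff
its center lies inside the geometry, with no area weighting of partial
pixels. The rule is deliberately simple enough to check against a
point-in-polygon enumeration oracle, and the county value is a *single*
zonal mean over the county∩boundary geometry rather than a mean of
sub-polygon means, which would implicitly weight unequal fragments equally.
Nodata pixels are excluded; zones capturing no pixel center yield missing
values.

## The synthetic world

`generate_region()` lays square counties on a grid in planar Cartesian meter
coordinates (no geodesy — buffers and hectare densities are metric). Block
groups tile each county exactly. Urban counties get a dense core
(urban-core land cover) inside a residential ring; rural counties get a
compact town (with probability 0.92, so a few counties genuinely lack an
urban area), one or two villages, forest patches, occasional ponds, and an
agricultural matrix. Census places cover towns, villages and incorporated
city areas; urban areas cover only the contiguous dense cores — so villages
appear in places but rarely in urban areas, reproducing the qualitative
mismatch between the two layers. Household counts per block group follow
log-normal density laws per land-cover label (medians 12, 1.5, 0.8, 0.05,
0.02 households/ha for core, town, residential, agricultural, forest), which
places urban cores far above the 1/ha threshold, towns mostly above it,
villages mostly between 0.1 and 1/ha, and farmland mostly below 0.1/ha —
the two residential-density schemes therefore select genuinely nested,
non-trivial subsets.

NDVI follows a per-class double-logistic annual curve, normalized so the
sampled maximum equals baseline + amplitude exactly: water 0/0; urban core
38/16; residential 42/25; agriculture 32/44 with a short steep season;
forest 48/28 with a long season. County-level heterogeneity enters through
three multipliers: an amplitude factor (U(0.92, 1.08)), independent season
onset/offset shifts (±0.8 months), and a log-uniform *shape* factor
(0.55–1.8) on the logistic steepness. The shape factor is the deliberate
decoupling device: a boxier curve raises the seasonal average at a fixed
annual maximum, so across counties TIN varies for reasons MXN cannot see.
Under the defaults this yields county-level TIN ≈ 15 ± 2 and MXN ≈ 67 ± 2
within the combined scheme with a TIN–MXN correlation near 0.6 — the same
scale relationship and moderate coupling seen in real county tables, where
TIN has roughly three times the relative spread of MXN. Gaussian observation
noise (default SD 2 percent) is added per pixel and period, then clipped to
[0, 100].

County health tables are generated by an explicit linear model. Nine
sociodemographic and behavioral covariates are drawn from uniform ranges
with urban/rural mean shifts loosely matched to published county summaries
(means only — the generator makes no calibrated distributional claim).
Exercise is `intercept + β·TIN(combined) + Σ γ_k·covariate_k + ε` with
planted β = 0.8 by default and ε ~ N(0, 4); the two health outcomes add the
realized exercise value as a predictor and carry a zero greenness
coefficient by default. All planted coefficients are returned in a truth
sidecar so tests never reverse-engineer them from outputs. With zero noise
the full pipeline returns the planted coefficients to machine precision;
with noise the estimator is unbiased across replicates and its 95%
confidence interval covers the truth at the nominal rate, because the fitted
model is exactly the generating model.

## Statistical battery

* Urban/rural comparisons use a two-sample t test per variable, gated by the
  classic mean-centered Levene test at α = 0.05: Welch's unequal-variance
  form when Levene rejects, the pooled form otherwise. The same formulas are
  exposed for printed summary tables (`t_from_summary()`), which is how the
  published comparison table is reconstructed from its group means and SDs;
  on raw samples the summary route and the raw route agree to 1e-12.
* The zoning grid fits 24 models (6 schemes × 2 metrics × null/adjusted);
  the scaling grid fits the adjusted model at four buffers of the combined
  scheme; the outcome models add exercise as a predictor for the two health
  outcomes. OLS goes through `stats::lm`, with standardized β = B·sd(x)/sd(y),
  and a rank check that names offending columns. Counties are unweighted
  observations; missing exposures are deleted listwise per model with n
  reported; no multiple-testing correction is applied anywhere.
* Correlations over the 12 scheme × metric exposure columns use pairwise
  deletion; zero-variance columns yield missing entries.
* BMI categories are lower-inclusive ([18.5, 25), [25, 30), [30, ∞)) — the
  verbal definitions ("between", "over") are ambiguous exactly at the
  boundaries, and a fixed convention beats an undocumented one. Urbanicity
  is a configurable population threshold, default 100,000; the alternative
  MSA-based 60,000 definition is available by passing that threshold rather
  than by a second code path.

## Numerical and design notes

* Geometry is a small exact-first kernel: axis-aligned rectangle unions use
  sweep (Klee) areas and exact containment; buffered rectangles keep the
  exact distance-to-rectangle predicate alongside the discretized ring; only
  unions of overlapping curved parts fall back to lattice sampling, whose
  membership is monotone, so nested buffers keep ordered areas at a fixed
  resolution.
* Dissolving a rectangle union decomposes it into disjoint rectangles and is
  idempotent; buffering by 0 is the identity.
* Ties for the longest growing-season run break toward the earlier run;
  all-nodata pixels propagate NA; TIN needs at least 4 valid periods.
* Determinism: every generator consumes only the config seed (stage offsets
  +1, +2 internally), so identical configs give byte-identical worlds,
  stacks and tables; replicate experiments derive per-replicate seeds from a
  base seed.
* Problem sizes: the default world is 94 counties of 12 km (48 × 48 pixels
  of 250 m, a 480 × 480 raster). Monte-Carlo experiments run the same 94
  counties at 3 km (12 × 12 pixels), a size chosen so that a full replicate
  chain stays around a quarter second while preserving the spatial
  structure; the replicate counts (500 recovery, 1000 null calibration, 100
  scheme-grid comparisons) are fixed in `scripts/acceptance.R`.

## What passing tests do and do not show

The generator emulates the *structure* of the real measurement problem —
nested boundaries with genuinely empty cells, two partially coupled
greenness metrics, covariates with urban/rural contrasts, a linear outcome
model — and the tests show the pipeline recovers known truth under that
structure. They do not validate the generator against real census
geographies (counties here are squares; block groups are equal-area tiles,
whereas real block groups are population-balanced and wildly unequal in
area), real phenology (one smooth season, no snow, drought or double
cropping, no cloud-induced nodata), or real survey error (covariates are
independent uniforms; real sociodemographics are correlated and spatially
autocorrelated). Spatial autocorrelation of residuals, survey weighting and
mediation analysis are out of scope by design. Published regression tables
from the motivating study design are not reproducible at desk scale because
the underlying county survey and satellite rasters are not deposited; the
package therefore reconstructs what is computable from printed summaries
(the urban/rural comparison table) and substitutes property-based evidence
(recovery, calibration, qualitative zoning pattern) for the rest.
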