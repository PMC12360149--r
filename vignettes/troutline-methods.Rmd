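---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(troutline)
```

`troutline` reconstructs a complete acoustic-telemetry movement-behaviour
analysis — detection cleaning, thermally defined seasons, horizontal and
vertical movement metrics, and mixed-model comparison of stocked versus wild
lake fish. This vignette records the science behind each stage, the
parameters that matter, the decisions taken where the design was genuinely
open, and what the test suite does and does not establish.

## The measurement problem

Passive arrays log a transmission only when a tagged fish is within
detection range of a moored receiver, with probability falling off with
range. Positions are therefore sparse, irregular, and biased toward
receiver locations. All downstream metrics are built to be robust to this:
centre-of-activity (COA) averaging, hexagonal-grid snapping, land-avoiding
interpolation, and fixed-size subsampling of depth records all exist to
control receiver-driven artefacts rather than to add modelling
sophistication.

## Detection cleaning

The cascade runs in a fixed order — spurious singles, dead fish, cohort
filters — because the dead-fish heuristics assume spurious rows are gone and
the full-season coverage test is defined on otherwise-clean data.

* **Spurious singles.** A detection is removed iff no other detection of the
  same tag at the same receiver lies within ±1 h. This is the symmetric
  neighbour reading of the usual "single detection over a period longer than
  one hour" rule; a pair exactly 1 h apart survives. The filter is
  idempotent and never reorders or edits surviving rows.
* **Dead fish.** Two rules: (a) a sensor-tagged fish whose entire depth
  record has standard deviation < 1 m (no vertical activity); (b) a terminal
  run of detections at a single station lasting at least `terminal_days`
  up to the end of the record. Field protocols leave the duration
  unstated, so it is a parameter (default 30 days) rather than a guess
  baked into code.
* **Cohort filters.** Each fish loses its release-season detections
  (behavioural disturbance after surgery), everything is clipped to the
  half-open study window `[start, end)`, and fish whose remaining record
  does not bracket at least one complete season (first detection at or
  before a season start, last at or after its end) are dropped. The
  bracketing reading of "detected for at least one full season" is the
  weakest defensible one; anything stronger (e.g. daily coverage) would
  discard most real fish.

## Biological seasons

Seasons are thermal states of the lake, not calendar quarters. The
experienced-temperature series (mean across sensor-tagged fish of each
fish's daily *minimum*) tracks the coldest habitat fish select; comparing it
to the near-surface series identifies stratification onset and breakdown.
The season state machine runs on the 7-day centred rolling mean of the
surface series with thresholds 8/17/15 °C:

* winter → spring at T ≥ 8 (the spring range is printed as "8–17", so 8 °C
  belongs to spring);
* spring → summer at T > 17 (strict, keeping spring's upper edge at 17);
* summer → fall at T < 15 (strict);
* fall → winter at T < 8 (strict);
* a spring that cools below 8 without reaching 17 closes as winter, with a
  warning (a no-summer year).

Boundary tie-handling at the exact threshold values is not specified
anywhere authoritative; the choices above keep printed ranges intact and
are documented as this package's convention, not as the original authors'.
The calendar partitions the series into half-open day intervals; a season
instance is a (label, year) pair, the year being that of the interval start
(so a winter spanning New Year belongs to its starting year). Thresholds
are configuration (`thresholds_config()`), not re-derived: they were fixed
by inspection of one system and transferred across years.

## Life history

Growth follows a von Bertalanffy daily-increment scheme,
dL/day = k(L∞ − L)/365.25, anchored at capture length. The increment has an
exact geometric solution, which the tests check against the continuous-time
closed form (difference < 0.5 mm over a year). Fish captured at or above L∞
keep their capture length. The published growth-rate source for this system
prints no parameters, so L∞ and k are configuration with defaults
(850 mm, 0.25 yr⁻¹) typical of slow-growing inland lake trout; any monotone
curve with the stated anchor and cap behaviours satisfies the contract.
Maturity: the cutoff is the lower edge of the smallest 25-mm bin at which
*every* group (stocked/wild × male/female) exceeds 50 % mature — 500 mm by
default — and a fish at exactly the cutoff is immature. For seasonal models
the categorical maturity value is taken at the season midpoint, the
categorical analogue of averaging length by season.

## Spatial metrics

The water graph is an 8-connected raster over water-cell centres (default
resolution 250 m, configurable; it must be finer than the narrowest passage
that should stay traversable). Between consecutive detections at different
stations the fish follows the straight segment when it stays in water, and
the graph shortest path otherwise; hourly positions are placed along the
route proportionally to elapsed time. Consecutive detections at one station
pin the fish there. Gaps of any length are interpolated — with sparse
arrays, dropping long gaps would discard most of the record — and each
point carries its enclosing gap length so users can weight or filter.
Occupancy proportions are computed over hours *with* estimated positions,
not calendar hours, matching the use of days-with-positions as a
random-effect covariate downstream. A point on a region boundary keeps the
previous point's region. The beta-compression transform
y′ = (y(n−1) + 0.5)/n maps {0, 1} strictly inside the unit interval
(a shift of about 0.001 at n = 500), preserves order, and fixes 0.5.

## Movement metrics

COAs are detection-count-weighted mean receiver positions per clock-aligned
1-h bin. Snapping them to a flat-top hexagonal grid with 1-km centroid
spacing deliberately discards sub-kilometre movement; seasonal distance is
the sum of centroid-to-centroid steps between consecutive same-season COAs,
and pairs spanning a season boundary count toward neither season. Grid
origin sits at the lake bounding-box corner and boundary points go to the
lowest adjacent cell id — orientation and origin are not identifiable from
any description of the method, so they are fixed for reproducibility.

**Days denominator.** Average daily movement divides seasonal distance by
the *difference* in days between the first and last COA of the season
(minimum 1). The plain-difference reading follows the phrase "number of days
between approximate positions" and the package's own worked example
(4 km over 2 days → 2 km/day); a `denominator = "days_with_coas"` flag
provides the other defensible reading (count of distinct COA dates).

## Depth metrics

A (fish, day, region) is analysed only with strictly more than 20
depth-bearing detections (21 qualifies, 20 does not), and each eligible day
is summarized from exactly 20 values drawn uniformly without replacement —
constant sample size keeps daily standard deviations comparable and damps
autocorrelation. The draw's sub-seed is recorded per row and one subsample
is drawn per fish-day, never redrawn per analysis. Vertical activity uses
the n−1 standard deviation. The station-depth covariate is
detection-weighted (each of the 20 values carries its station's depth);
"stations involved with each subset" could also mean the distinct-station
mean, available via `station_weighting = "distinct"`. Subsampling is not
stratified by time of day — nothing in the protocol suggests it was.

## Mixed models

Four response families are used: Poisson (log) for region counts, beta
(logit) for compressed occupancy proportions, Tweedie (log) for
zero-inflated distances and vertical activity, and lognormal (Gaussian on
the log response) for positive depths. `glmmTMB` is not available in this
toolchain, so models are fitted with `mgcv::gam` using random-intercept
ridge smooths (`bs = "re"`), which supports all four families under one
maximum-likelihood interface (`method = "ML"`, so AICs are comparable
across fixed-effect structures). The Tweedie power parameter is profiled by
`mgcv::tw()` within (1, 2) rather than over an explicit grid — the same
contract by different machinery. Continuous random-effect variables
(days-with-positions, station depth) are binned into quintile factors:
continuous random intercepts are ill-defined, and quintiles keep the
variance-absorbing role without inventing a functional form.

Selection enumerates every admissible fixed-effect subset (an interaction
only with both main effects), ranks converged fits by AIC, and returns the
fewest-parameter model within 2 AIC units of the minimum (ties → lower
AIC). Marginal means average the link-scale linear predictor over a full
factorial reference grid with numeric covariates at their means and random
effects at zero; pairwise contrasts use the studentized-range (Tukey)
adjustment with large-sample normal degrees of freedom, which reduces
exactly to the unadjusted z-test for a two-level factor. Predictions are
conditional (random effects at zero); for the lognormal family they are
`exp(μ)`, the conditional median, with no σ²/2 back-transformation — a
deliberate choice kept consistent between contrasts and predictions.
Because model selection precedes inference, the realized type-I error of
the select-then-contrast pipeline exceeds the nominal α; the test suite
verifies planted-null behaviour at the fit level rather than claiming
selection-adjusted coverage.

## The synthetic generator

The generator states a world with the structure the analysis assumes:

* tags transmit with independent uniform(80 s, 160 s) delays;
* detection probability follows p(r) = 1/(1 + exp((r − r50)/s)) fitted
  exactly through (250 m, 0.70) and (500 m, 0.30) — r50 = 375 m; only the
  two point estimates are documented for the real system, so a
  two-parameter logistic is the minimal curve through them;
* fish follow biased correlated random walks (10-min internal step) with
  fixed per-step length, so realized track length equals the configured
  seasonal speed; multi-day residency bouts (default 3 days) draw target
  regions from configurable weights, emulating site fidelity while keeping
  transit a small fraction of time;
* daily depth preferences are seasonal normals truncated to the local
  bottom; within-day wobble (2 m) gives live sensor fish measurable
  vertical activity;
* surface temperature is a smooth annual sinusoid (2–24 °C, minimum in
  early February); experienced temperature equals surface below 8 °C and
  rises at one quarter the surface rate above it, capped at a 9 °C
  hypolimnion — reproducing deviation onset at the 8 °C crossing and a flat
  stratified summer;
* planted dead fish freeze (position and depth) at a configurable track
  fraction; `de_mode = "nearest"` is a noise-free validation mode in which
  exactly the nearest in-range receiver logs each transmission.

What it does **not** emulate: diel rhythms (undocumented for this system,
so deliberately absent), tag collisions, thermal effects on detection
range, bathymetry beyond a per-region depth, and hydrodynamic temperature
structure. A green recovery test therefore establishes that the estimators
recover the stated world's truth under honest detection sparsity — not that
they are unbiased for any real lake.

Runtime choices in the acceptance suite are scale-downs, stated once:
recovery runs use 14–30-day seasons, 20–100 fish, and coarser walk steps
(30–60 min) where the 10-min default adds nothing but time. The
`de_mode = "nearest"` mode is used exactly where the criterion's
quantization-bound premise requires a noise-free array; under probabilistic
multi-receiver detection, COA jitter *inflates* distance estimates on dense
arrays — a real and documented failure mode of the COA-plus-hex metric, not
of the implementation.

## Known limitations

* Region polygons must be pairwise disjoint and axis-aligned rectangles are
  the tested shape for synthetic lakes; arbitrary polygons are supported by
  the geometry but not exercised by the generator.
* The water graph shares one resolution lake-wide; narrow channels thinner
  than the resolution disconnect.
* The dead-fish terminal-residency rule cannot distinguish a dead fish from
  a genuinely sedentary one next to a receiver; D trades recall against
  false positives and is the user's call.
* Beta and Tweedie mixed models rely on `mgcv`'s extended families; their
  AICs use the conditional (effective-degrees-of-freedom corrected)
  definition, which is the comparable quantity within this machinery but
  not numerically identical to `glmmTMB`'s marginal AIC.
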