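---
title: "Methods: home range, movement and habitat selection in channel-dissected mangrove landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: home range, movement and habitat selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangrovemove)
```

`mangrovemove` analyzes GPS telemetry of large territorial carnivores in
mangrove archipelagos, where islands of forest are separated by tidal water
channels of widely varying width. This vignette is the package's account of
its methods: the estimators, the synthetic generator that backs the tests,
the tunable parameters, the numerical choices, and the limitations a user
should know about.

## Home-range estimation

**Minimum convex polygon.** `compute_mcp()` builds the convex hull of the
fixes. For a level below 100%, the `ceiling((1 - p/100) * n)` fixes farthest
from the arithmetic centroid are removed first. Distance-from-centroid is
one of several published trimming rules; it is the simplest and is stated
explicitly here because the choice affects areas by a few percent. Collinear
fixes yield a degenerate zero-area result with a warning rather than an
error, so screening scripts can proceed.

**Fixed-kernel utilization distribution.** `compute_fixed_kernel_ud()`
averages circular bivariate Gaussian kernels centered on the fixes. The
bandwidth `h` is the kernel standard deviation *in meters*; the study
default is `h = 1000` m, a deliberate choice for animals whose daily
displacement is a few kilometers. The grid pads at least `4h` beyond the fix
extent so that less than 1e-4 of any kernel's mass is lost, and the grid is
renormalized to integrate to exactly 1. The default cell is `h/10`; cells
coarser than `h/4` are refused because isopleth areas then quantize visibly.

**Isopleths.** The level-*p* isopleth is the smallest-area superlevel set of
the density holding probability *p*/100. `extract_isopleths()` computes it
exactly on the grid by accumulating cells in decreasing density order —
no contour interpolation, so areas are monotone in *p* by construction and a
single-fix UD reproduces the bivariate-normal closed form
(area = −2 ln(1 − p/100) π h²; 18.82 km² at p = 95, h = 1000 m) within the
grid quantization (±2% at cell = h/10). Boundary polygons for display or
GeoJSON export come from contour tracing of the same threshold
(`isopleth_polygons()`), but areas are always reported from the cell count.

**Core area.** Plotting isopleth area against level gives a rising curve;
the core is read off at its inflection. `detect_core_isopleth()` defines the
inflection as the level maximizing the second forward difference of area
over level (ties toward the higher level). A profile that is linear within
1e-9 relative tolerance has no bend and returns `NA` rather than inventing a
core. The detector is invariant to uniform rescaling of all areas.

**Water masking.** Channels wider than 1 km are treated as non-habitat:
`mask_water()` subtracts their overlap with the home range. MCP polygons are
clipped exactly against each channel rectangle (Sutherland–Hodgman, both
convex); kernel ranges drop grid cells whose centers fall in a wide channel.
Overlapping wide channels would be double-subtracted; the generator never
overlaps channels of that size, and field channel layers rarely do.

**Asymptote.** `asymptote_curve()` recomputes the range on the first 50,
100, … fixes and flags the first sample size where the next increment adds
less than 5% (configurable) of the current area.

**Summaries and density.** `summarize_home_ranges()` averages non-excluded
animals by sex (SE = sd/√n) and rounds half-up at two decimals — the
convention of printed summary tables, where a mean of 56.485 km² prints as
56.49 (base R's round-half-to-even would print 56.48).
`estimate_density()` treats mean core areas as exclusive territories tiling
the land: `n_sex = round(land / core_sex)`, SE ranges from
`land / (core ± SE)`, density = `100 (n_f + n_m) / land` to one decimal.
This is a deliberate idealization: it ignores the dispersing segment of the
population and assumes cores tile without gaps, so it is a crude first
estimate, not a substitute for capture–recapture.

## Movement metrics

Days are bounded by local civil midnight at a configured UTC offset
(default +05:30); the day convention matters for day-level statistics and is
therefore explicit. Only days with at least 12 fixes are usable for daily
distance — about half the fixes of a 1-h schedule at realistic acquisition
rates — which bounds the downward bias of summing fix-to-fix chords.
`hourly_activity()` assigns each step's distance to the local hour of the
step start. Steps faster than 10 km/h are flagged, never dropped: bursts of
over 5 km/h are real, but faster apparent speeds usually indicate a position
error.

Tide phase is assigned from a lunar calendar of new/full moons: the 8-day
window `[syzygy − 3, syzygy + 4]` is spring, the remaining ~6 days neap. An
8-day window cannot be symmetric on integer days; this anchoring keeps
`syzygy + 4` in spring and `syzygy + 5` in neap.

`fit_movement_model()` fits `log(distance) ~ period + tide + (1 | animal)`
with lmer (REML, Satterthwaite t-tests via lmerTest). The model itself is
standard; the package's contribution is the data pathway into it. Zero
distances are replaced by half the minimum positive distance before the log;
with a single animal the random intercept is dropped with a warning.

## Channel crossings and the barrier test

`detect_crossings()` records one crossing per maximal intersection of a
consecutive-fix segment with a channel corridor; re-entering the same
channel later in the day counts again. Channels are straight constant-width
corridors (centerline + width), so segment–channel intersection is exact
slab clipping.

The availability reference is a random-walk null model
(`generate_null_paths()`): for each observed daily path, 5 random
trajectories with the same step count, step lengths uniform within the
observed path's [min, max] step length, a fresh uniform heading at every
node, the observed start point, and whole-path rejection until no node
leaves the pooled-fix polygon and none lands in water. Rejection sampling
can exhaust its budget when a day starts on a narrow land sliver;
`allow_partial = TRUE` then keeps the accepted subset, matching the field
convention of "5 per path minus failures". `crossing_chisq()` bins crossings
by width (50-m bins to 1000 m, then 500-m bins, left-closed), scales the
null profile to the observed total, merges adjacent bins until every
expected count reaches 1, and reports Pearson's X² with df = bins − 1.

**A calibration warning.** The Pearson test treats crossing counts as
independent. They are not: a path that wanders along a channel crosses it
several times, and those repeats are strongly dependent. For an isotropic
random walk the probability of re-crossing a line it has just crossed is
roughly 0.45 *independent of step scale*, so observed counts are
overdispersed by a factor near 2, and the test rejects a true null far more
than 5% of the time. Simulation with this package's own generator — even in
the most favorable case where the "observed" path is drawn from the null
family itself — puts the realized type-I error near 20–30% rather than 5%.
Persistent (straight-moving) walkers reduce the repeat-crossing dependence
but then differ systematically from the uniform-heading null family, which
the test detects instead. Users should read a significant barrier X² as
evidence to be weighed alongside the per-bin profile (wide channels crossed
far below availability), not as an exact p-value; the packaged experiments
report the realized rejection rates honestly (see the experiment designs
below).

## Habitat selection

Use is the share of fixes per habitat class; availability is the class
composition of the animal's 95% FK home range (cell centers of the UD grid
inside the isopleth, looked up in the habitat raster). Compositional
analysis forms, per animal, `d_i = ln(u_i/u_ref) − ln(a_i/a_ref)` for a
reference class (default Water; the statistic is invariant to the choice,
and the package tests that invariance). Wilks' Λ is the ratio of the
determinants of the centered and raw cross-product matrices of `d`;
X² = −N ln Λ on D − 1 degrees of freedom. Zero use values are replaced by
0.01 before the log-ratio transform (the customary substitution; the
analysis is insensitive to the exact value at realistic sample sizes). The
preference order comes from the pairwise matrix of mean log-ratio
differences with per-pair t statistics, ranked by pairwise wins. With fewer
animals than classes the cross-product matrix is singular; the test fields
are then NA and only the ranking is returned, with a warning. An optional
permutation p-value (animal-wise sign flips of `d`) is available for small
N. Ivlev's electivity `E_i = (u_i − a_i)/(u_i + a_i)` is provided for
per-animal graphics.

## The synthetic generator

`generate_landscape()` lays straight constant-width channels spanning the
extent (widths log-uniform in 30–2500 m, so narrow creeks dominate), then
thresholds a smoothed Gaussian random field on the remaining cells at the
quantiles that hit the target class fractions. The default fractions are the
mapped shares of a mangrove tiger reserve — Water 41.48%, Phoenix 36.92%,
Ceriops 11.91%, Barren 5.2%, Avicennia–Sonneratia 4.52% — renormalized to
sum to 1 (the printed percentages total 100.03%). Land classes stack in an
elevation-like order (Avicennia–Sonneratia lowest, Phoenix highest),
mimicking tidal zonation. Realized fractions land within ±2 percentage
points of the target; identical seeds give identical rasters.

`simulate_tiger()` runs a biased correlated random walk on an hourly clock:

| parameter | default | meaning |
|---|---|---|
| `step_scale` | 199 m | mean hourly step at unit activity |
| `turning_concentration` | 1 | wrapped-normal heading persistence (0 = uniform) |
| `attraction_strength` | 0.4 | pull toward the home center |
| `habitat_weights` | AvicSonn 5 > Phoenix 4 > Ceriops 3 > Barren 2 > Water 0.05 | endpoint acceptance weights |
| `crossing_halfwidth` | 150 m | width at which crossing probability halves: `2^(−w/hw)` |
| `activity_profile` | dawn-peaked | 24 hourly multipliers, max at 07 h local |
| `fix_interval_hours` / `fix_success_prob` | 1 h / 0.666 | GPS schedule and acquisition rate |

`step_scale = 199` m was calibrated once so that the realized mean daily
travel over 200 days is ≈ 4.6 km under the default landscape; the dawn peak,
the 66.6% acquisition rate, the 1–3 h schedule and the preference order are
the study conditions the generator emulates. Step lengths are shape-2 gamma
by default; `step_length_dist = "uniform"` matches the null-path family and
exists for calibration experiments. The ground-truth record keeps realized
daily distances, per-channel crossing proposals and acceptances (tallied on
land-endpoint proposals so the width-dependent factor is identifiable), and
hourly habitat occupancy. `estimate_crossing_halfwidth()` recovers the
planted half-width from the per-channel acceptance ratios by a weighted
log-linear fit; at 500 simulated days it lands within ±25%.

What the generator does *not* emulate: tidal inundation dynamics (the water
mask is static), territorial interaction between animals, GPS position
error, and habitat-dependent step lengths. Passing tests therefore show the
estimators are correct on data that satisfy their assumptions, not that the
assumptions hold for any particular field dataset.

## Fixed experiment designs

Two simulation experiments are packaged so the test suite and the acceptance
script share one definition.

*Barrier test* (`barrier_test_experiment()`): a channels-only landscape
(eight corridors of widths 30–500 m, ~15% water — kept modest so whole-path
rejection sampling of null trajectories stays feasible) with four simulated
tigers whose home centers are scattered across the extent and whose fixes
are pooled into one common polygon, as the field design pools all collared
animals — with a single animal the availability polygon is bounded by the
very barriers under test and the comparison loses its contrast. The type-I
arm (60 days, `crossing_halfwidth = Inf`) uses walkers matched to the
null-path family (uniform headings and step lengths, no attraction, flat
activity, water endpoints forbidden), the closest the design can come to an
exactly-true null; its realized rejection rate quantifies the
anticonservatism discussed above. The power arm (200 days, half-width 200 m)
uses the simulator's study-condition movement, with complete hourly fixes
because crossing detection from gappy fixes would run multi-hour straight
chords through channels the animal never crossed. Power is high (~85–90% of
replicates reject) but not perfect: when a territory sits pocketed between
wide channels, even the pooled availability under-represents them — the
hull-bounded null model is structurally blind to barriers that coincide
with range edges.

*Preference recovery* (`preference_recovery_experiment()`): six tigers, 20
days each, on a 15-km landscape, with planted weights
AvicSonn 8 > Phoenix 4 > Ceriops 2 > Barren 1 > Water 0.25 (factor-2
separation between adjacent ranks — distinct enough that a 20-day track
identifies the order, which is what "ranked weights" must mean for a
recovery experiment to be well-posed). Each replicate runs the full
use/availability pipeline including the 95% FK availability, then checks
that the compositional ranking equals the planted order.

Problem sizes throughout (60–200 simulated days, 40–100 replicates,
15–20 km landscapes at 50-m cells) were chosen as the smallest that give
stable rates on a single CPU.

## Numerical choices and edge cases

- Bins and windows are left-closed: a 1000-m channel falls in [1000, 1500);
  06:00 is day, 18:00 is night; `syzygy + 4` is spring.
- Duplicate timestamps within an animal are an error (a GPS schedule cannot
  emit two fixes at one instant), not averaged away.
- Fix CSVs round-trip losslessly (ISO-8601 UTC timestamps, `%.17g`
  coordinates).
- All coordinates are an abstract projected plane in meters; geographic
  input must be projected upstream.
- The pipeline derives one seed per stage from the global seed, so stages
  can be re-run in isolation reproducibly.

## Known limitations

- The crossing chi-square anticonservatism described above is a property of
  the method, not of this implementation; treat barrier p-values
  qualitatively.
- The exclusive-core density is a deliberate idealization (no dispersers,
  perfect tiling).
- MCP areas depend on the trimming rule; only distance-from-centroid is
  implemented.
- No LSCV/plug-in bandwidth selection, Brownian-bridge or autocorrelated
  kernel estimators, step-selection functions, or hidden-Markov behavioral
  segmentation — the estimators here are the classical ones their outputs
  are compared against.
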