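# mangrovemove

Telemetry analysis for tigers (and other large carnivores) living in mangrove
archipelagos — landscapes of islands dissected by tidal water channels. The
package takes GPS fix tables and a habitat map and produces the standard
space-use results of a collaring study:

- **Home ranges**: 95% minimum convex polygons (MCP) and fixed-kernel (FK)
  utilization distributions (bivariate Gaussian kernel, bandwidth `h` in
  meters), isopleth area profiles from 5% to 95%, detection of the core-area
  isopleth at the inflection of the area-vs-level curve, exclusion of water
  channels wider than 1 km as non-habitat, and area-vs-sample-size asymptote
  diagnostics.
- **Movement**: daily travel distance over days with at least 12 fixes,
  hourly activity profiles, and a linear mixed model
  `log(distance) ~ day/night + spring/neap tide + (1 | animal)`.
- **Channel crossings**: detection of channel crossings along daily paths, a
  random-walk null model (5 matched random trajectories per observed path,
  rejected if they leave the pooled-fix polygon or land a node in water), and
  a chi-square test of whether crossings are proportional to availability by
  width bin (50-m bins to 1000 m, then 500-m bins).
- **Habitat selection**: use (share of fixes per class) versus availability
  (class areas inside the 95% FK home range), compositional analysis
  (log-ratio Wilks' lambda, `chi^2 = -N ln(Lambda)`, `df = D - 1`, pairwise
  ranking matrix) and Ivlev's electivity `E = (u - a) / (u + a)`.
- **Density**: exclusive-core extrapolation — `n_sex = land / core_sex`
  rounded, density `100 (n_f + n_m) / land` per 100 km² with SE ranges.

A synthetic generator (`generate_landscape()`, `simulate_tiger()`) produces
mangrove-like habitat rasters, width-attributed channel networks and biased
correlated-random-walk tiger tracks with known ground truth (habitat weights,
crossing reluctance half-width, activity profile), so the entire pipeline is
testable without field data.

## Worked example

```r
library(mangrovemove)

# the published per-animal areas (km^2): two included animals per sex
tab <- data.frame(
  animal_id = c("M1", "M2", "F1", "F2"),
  sex       = c("M", "M", "F", "F"),
  estimator = "FK", level = 75,
  area_km2  = c(32.76, 83.78, 42.06, 27.55),
  excluded  = FALSE, exclude_reason = "")
summarize_home_ranges(tab)$summary
#>   sex estimator level n mean_km2 se_km2
#> 1   F        FK    75 2    34.81   7.26
#> 2   M        FK    75 2    58.27  25.51

estimate_density(1645, 34.81, 7.26, 58.27, 25.51)
#> exclusive-core density: 47 females (range 39-60), 28 males (range 20-50)
#>   4.6 animals / 100 km2 (range 3.6-6.7) on 1645 km2 land
```

So a reserve with 1645 km² of land, a mean female core of 34.81 km² and a
mean male core of 58.27 km² accommodates about 47 territorial females and 28
males — roughly 4.6 tigers per 100 km².

An end-to-end synthetic run:

```r
report <- run_pipeline(default_pipeline_config(seed = 4, outdir = "run1"))
#> - acquisition rate: 0.656
#> - usable days: 172
#> - mean daily distance: 3.77 km
#> - activity peak hour: 6
#> - crossing test: X2 = 8.02, df = 2, p = 0.0182
#> - habitat preference: AvicSonn > Phoenix > Ceriops > Barren > Water
```

The six simulated tigers prefer Avicennia-Sonneratia most and water least
(the generator's planted ordering); the mean fix-to-fix daily distance of
3.77 km sits below the simulator's true mean path length (~4.6 km/day)
because a 66.6% acquisition rate replaces parts of each day's path with
straight chords.

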