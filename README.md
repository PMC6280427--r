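# vesselbird

Detecting and quantifying individual interactions between
GPS/accelerometer-tracked seabirds and GPS-monitored fishing vessels.

Central-place-foraging seabirds such as shearwaters scavenge fisheries
discards. Area-overlap analyses cannot tell whether a bird actually
attended a vessel or merely foraged nearby, so `vesselbird` implements an
individual-level detection procedure for researchers working with joint
biologging (GPS at ~5 min, tri-axial accelerometry at 25 Hz) and Vessel
Monitoring System (VMS) data:

1. **Behaviour classification.** Vectorial Dynamic Body Acceleration,
   \(VeDBA = \sqrt{a_x^2 + a_y^2 + a_z^2}\) (dynamic components after
   1-s static removal), flags *sitting on the water*
   (0.1 g ≤ VeDBA ≤ 1 g plus a ground-speed filter); spectral k-means on
   1-s windows of |Z| separates *flapping* from the rest, and short gaps
   between flapping bursts become *gliding*. Daily flight time and the
   daily VeDBA sum summarise effort.
2. **VMS regularization.** Native pings (every 1–2 h) are linearly
   interpolated onto a common 10-min grid, as if all vessels transmitted
   simultaneously, and classified fishing/steaming by per-gear speed
   filters.
3. **Approach events.** For each bird fix at time *t*, the single grid
   ping per vessel in [*t*−5′, *t*+5′) gives a bird–vessel distance
   series; maximal runs of ≥2 consecutive fixes with strictly decreasing
   distance, a cumulative drop ≥500 m, and a start within the 30-km
   attraction distance are approach events.
4. **Interaction distance.** The percentage of sitting behaviour is
   binned by vessel distance (250-m bins); a two-segment linear
   regression — ordinary least squares on each side of every candidate
   split, minimal total RSS — estimates the breakpoint below which
   sitting sharply increases. A smoothed nonparametric bootstrap over
   bins gives the 95% CI. Approaches whose minimum distance reaches
   inside the breakpoint are validated *interaction events*.
5. **Group comparisons.** Linear mixed models (REML, bird identity as
   random intercept) of daily VeDBA, daily flight time, trip length and
   maximum colony distance on sex × interaction status; chi-square tests
   of gear preference and sex differences.

No tracking data are distributed; a first-class synthetic-data generator
(`sim_config()`, `simulate_dataset()`, `synthesize_accel()`) emits all
three data streams with complete ground truth (behaviour labels, trips,
planted attendance bouts, a known true interaction distance), so every
stage is testable end to end.

## Worked example

```r
library(vesselbird)

cfg <- sim_config(n_birds = 10, n_vessels = 8, days = 5, seed = 1)
ds  <- simulate_dataset(cfg)

# ground-truth sitting fractions stand in for the accelerometer chain here;
# with real data use add_sit_fraction(fixes, ethogram(acc, fixes)$seconds)
sit_fixes <- truth_sit_fraction(ds$fixes, ds$plan, cfg$sit_prob_inside)

res <- run_pipeline(ds$fixes, ds$vessels_native, sit_fixes, cfg$colony,
                    seed = 1)
res$fit
#> Interaction distance: 1.25 km (95% CI 0.97-2.53 km)
#>   model: split | slopes: -14.03 / 1.05 %/km | RSS: 572.739 | bins: 19
nrow(res$events)            # 74 validated interaction events
autoplot(res$fit)           # binned sitting % vs distance with the fit
```

The estimate of 1.25 km sits one half-bin from the generator's planted
1.28 km interaction distance; the 74 events are the approaches that
reached inside it. Trip metrics and the INT factor feed the mixed
models:

```r
head(res$trip_table, 2)
#>   bird_id trip_id duration_days category trip_length_km max_colony_distance_km
#> 1 B01     B01_T01         0.455 short              152.                   52.3
#> 2 B01     B01_T02         0.333 short              181.                   75.8

rec <- simulate_trip_records(seed = 8)   # planted Table-2-scale contrasts
tidy(fit_lmm(rec, "daily_flight_time_h", transform = "none"))
#>   term            estimate std.error statistic   df1   df2  p.value
#> 1 (Intercept)        4.70      0.348    183.       1   125 2.95e-26
#> 2 sexM               0.879     0.446      3.89     1   125 5.09e- 2
#> 3 int_flagINT_YES    0.960     0.267     12.9      1   125 4.70e- 4
```

The recovered interaction effect on daily flight time (0.96 ± 0.27 h)
matches the planted contrast of 0.94 h (6.22 vs 5.28 h).

A thin command-line wrapper lives in `inst/scripts/vesselbird.R`
(`simulate`, `vms`, `trips`, `run-all`).

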