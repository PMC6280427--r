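---
title: "Methods: detecting seabird-fishing vessel interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting seabird-fishing vessel interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselbird)
```

`vesselbird` detects individual interactions between central-place-foraging
seabirds and fishing vessels from three asynchronous data streams: bird GPS
fixes (nominal 5-min interval), tri-axial accelerometry (25 Hz), and VMS
vessel pings (native 1-2 h cadence). This vignette explains the model behind
each stage, the parameters that matter, the statistical design decisions that
were genuinely open, and what the synthetic-data generator does and does not
emulate.

## Behaviour from acceleration

The behavioural currency is VeDBA, the norm of the three dynamic acceleration
components. `compute_vedba()` estimates the static (gravitational) component
per axis with a centred running mean and subtracts it.

The phrase "1-s smoothing" in the DBA literature is ambiguous: it can mean
the static-estimation window or a smoothing of the VeDBA series itself. We
take the first reading (the standard DBA construction) as the default
(`static_window_s = 1`); the second is available as `smooth_vedba = TRUE`.
The window must cover at least two samples; series shorter than the window
are an error rather than silently unsmoothed.

*Sitting on the water* is assigned per second when mean VeDBA lies in the
0.1-1 g band - interpreted as wave-induced motion of a floating bird; below
the band the bird is motionless on land or gliding, above it it is in
flapping flight - and the GPS-derived ground speed does not exceed
`speed_max`. The band is applied to per-second means (not per-sample
values): per-sample VeDBA is dominated by accelerometer noise, while the
wave signature is stable at the 1-s scale. The speed threshold is not fixed
by the sitting band itself; we default to 2 m/s, comfortably above drift and
below flight (~10 m/s), and derive per-second speeds by linear interpolation
of the 5-min segment speeds at their midpoints. Interpolated speeds bleed
across behaviour boundaries; this is the main residual error source of the
classifier and the reason isolated sub-5-min sitting bouts are hard to
recover (see Limitations).

*Flapping* is found by clustering the amplitude spectra of 1-s windows of
|Z| with k-means (k = 2, 10 restarts, fixed internal seed so results are
reproducible without touching the caller's RNG). The cluster with the higher
mean peak amplitude inside the 2-8 Hz wingbeat band is flapping. If the two
clusters' peaks differ by less than 10% (relative), the signal carries no
flapping structure and no window is flagged - this covers all-noise and
constant streams without raising an error. Because k-means partitions are
scale-equivariant, doubling signal amplitude leaves labels unchanged.

*Gliding* is the interval between two flapping events: a non-flapping run
bounded on both sides by flapping and no longer than `max_gap_s` (default
30 s - long enough for shearwater glide phases, short enough not to absorb
rests on the water; the boundary-on-both-sides rule keeps leading and
trailing time out). Remaining seconds are SIT if the sitting classifier
fired, else OTHER.

Daily summaries use local (UTC+2) calendar days: daily flight time is the
summed FLAP + GLIDE duration in hours; the daily VeDBA sum adds the mean
VeDBA of every 5-min interval, so its magnitude scales with recording
coverage and is comparable only within a study design.

## VMS regularization

Native pings are linearly interpolated in lat/lon onto a global 10-min grid
aligned to the UTC hour, so all vessels appear to transmit simultaneously.
Linear (rather than spline) interpolation is deliberate: it is deterministic,
exact for constant-velocity legs, and its error is small relative to the
250-m analysis bins when vessel legs are quasi-linear. Grid-point speed is
the bracketing segment's great-circle distance over its duration; gaps
longer than `max_gap_h = 4` h (more than twice the native interval) are
never bridged. Activity is classified by per-gear speed bands (trawl
1.0-4.5 kn, purse seine 0-2.5 kn, longline 3-7 kn, all configurable);
unknown gears get `activity = "unknown"`.

## Approach events and the interaction distance

For each bird fix at time $t$, the half-open window $[t-5', t+5')$ contains
exactly one grid ping per vessel (the half-open convention is what makes
uniqueness exact on a 10-min grid); pairs beyond 50 km are dropped. Within
each bird-vessel series, approach events are maximal runs of temporally
consecutive fixes (gap tolerance 1.5 x the nominal interval) with strictly
decreasing distance, cumulative decrease >= 500 m, and a start inside the
30-km attraction distance. "Gradually decreased by at least 500 m" admits a
per-step reading too; both are implemented (`rule = "per_step"`), the
stricter cumulative reading is the default. Runs that begin farther out are
trimmed to their first fix inside 30 km rather than discarded - the
attraction distance caps where attraction can begin, it is not a veto on the
whole run.

Only at-sea fixes (outside the colony departure radius) enter the pairing:
interactions are a foraging-trip phenomenon, and without this restriction a
vessel steaming past the colony would register an "approach" for every bird
at its nest, since the distance series does not know which party moved.

The interaction distance is estimated from the pooled distance profile:
pairs are binned at 250 m, each retained bin averages the percentage of
sitting behaviour, and bins with too few pairs are dropped. The retention
threshold scales with data volume (110 pairs per bin at 4500 total, floor
5), so sparse synthetic runs keep proportionally supported bins.

### The breakpoint estimator

`fit_breakpoint()` fits a two-segment linear model by evaluating, at every
candidate split between adjacent bins, an ordinary least-squares line on
each side, and choosing the split with minimal total RSS (computed in O(n)
via prefix sums; exact ties go to the smaller breakpoint). Two design
decisions deserve explanation:

- **Side-wise OLS rather than a continuous broken stick.** When the true
  sitting probability steps at the interaction distance (the behavioural
  model here: a bird is either attending a vessel or not), the continuous
  broken-stick knee is not a consistent estimator of the step location - on
  step-shaped profiles its minimiser sits near 1.5x the true distance,
  because the continuity constraint forces the left segment to smear the
  jump. The side-wise model locates the jump itself. The continuous
  profiled variant (`model = "continuous"`, grid step `bin_km/10`) is kept
  for profiles that genuinely look like two joined trends.
- **Plateau midpoint and a smoothed bootstrap.** The split model's RSS is
  piecewise constant in the breakpoint: the data identify it only up to the
  interval between the two adjacent bin centres. We report the midpoint of
  that RSS plateau, and the nonparametric bootstrap (resampling bins,
  percentile interval, fixed seed) draws each replicate's breakpoint
  uniformly over its plateau. A naive bootstrap of the lattice-valued
  estimator collapses to a point mass whenever the true distance falls on a
  bin edge and its interval has zero width and zero coverage; integrating
  the plateau restores honest interval behaviour at the bin resolution.

Degenerate inputs are refused loudly: fewer than 4 bins, or an RSS profile
flat to within 1e-12 across all candidate splits (a single straight line),
raise errors rather than returning an arbitrary knee.

Approaches whose minimum distance reaches inside the fitted breakpoint
(closed boundary) are validated as interaction events; the rest are birds
that headed toward a vessel but broke off.

## Group comparisons

Trips are segmented at a configurable colony departure radius (default
2 km; the choice is not critical because the bounding inside fixes are
included in the trip, so trip length integrals start at the colony).
Excursions with fewer than 3 at-sea fixes are GPS jitter, not trips. Trips
up to 3 days are `short` - the analysis stratum for all group comparisons.

The four responses (daily VeDBA sum, daily flight time, trip length,
maximum colony distance) are modelled with `nlme::lme` (REML) on sex and
interaction status with a random intercept per bird. A Shapiro-Wilk screen
(alpha = 0.05) on the residuals of the untransformed ordinary fit decides
the log transform when `transform = "auto"`. F statistics are squared Wald
t ratios with denominator degrees of freedom `n - p` (observations minus
fixed-effect parameters); this is a reporting convention common in the
field's literature, documented rather than defended as exact small-sample
inference. If the mixed fit fails (e.g. one trip per bird), the function
falls back to ordinary regression with a warning - for balanced designs the
fixed-effect estimates coincide anyway.

Chi-square tests are Pearson without continuity correction by default
(switchable): gear preference as a 1-df goodness-of-fit of trawler vs
non-trawler interaction counts against fleet availability, and sex by
interaction status as a 2x2 table.

## The synthetic study

The generator (`sim_config()` and friends) defines the study conditions:
a colony on a small Mediterranean island, birds sampled every 5 min,
25-Hz accelerometry, vessels reporting native pings every 60-90 min, a
planted interaction distance of 1.28 km inside a 30-km attraction distance,
sitting probabilities of 0.8 inside and 0.2 while milling outside, a 4-Hz
wingbeat, and half the birds scavenging. Scavengers commute to the fishing
grounds, mill around an attended vessel at 1.5-4.75 km, approach it in
direct flight and follow it inside the interaction distance for 1-2.5 h
(sitting bursts alternating with catch-up flight, so their net speed stays
at the vessel's towing speed); non-scavengers forage at natural patches in
the opposite sector. Vessels tow long quasi-linear hauls at gear-typical
speeds, turn in wide arcs, stay on a 10-km leash around spaced-out
operating centres and keep 12 km off the colony island - all properties of
real fleets that also keep linear ping interpolation honest.

Ground truth is two-layered: *planted events* are the scheduled attendance
bouts (each reaches inside the true interaction distance by construction)
and anchor detection sensitivity; *truth runs* are all episodes, scheduled
or chance, in which a bird genuinely came inside the true distance, and
adjudicate false alarms - a detection of a real chance encounter is a
correct detection, not a false positive.

What the generator does **not** emulate: currents and wind, bathymetry,
energetic calibration of VeDBA magnitudes, device error in the bird GPS,
multi-colony fleets, or birds foraging near vessels without attending them.
Passing tests therefore demonstrate that the pipeline recovers what was
planted under realistic sampling and VMS-interpolation error; they do not
certify performance on real data, where the behavioural repertoire is
richer and the fishing-ground geometry less tidy.

Planted effect sizes for the group models mirror field-scale magnitudes:
interaction raises daily flight time from 5.28 to 6.22 h and the daily
VeDBA sum from 38.63 to 44.77 (partly mediated by flight itself, slope 3
VeDBA units per hour), trip lengths are log-normal around 243 vs 375 km,
and a sex-by-interaction effect of 9 VeDBA units (females higher when
interacting) is planted on VeDBA only - large enough to be detectable at
the simulated sample size (32 birds x 4 trips) with ~90% power, so a
detection-rate test is informative rather than a coin flip.

## Problem sizes and numerical conventions

The test suite and acceptance script run, by design, at desk scale: 150
breakpoint-recovery replicates of 5000 pairs each; detection studies of 10
birds x 5 days x 8 vessels (50 bird-days); 12 bird-hours of 25-Hz
accelerometry per ethogram check; 50 mixed-model replicates of 128 trip
records. One master seed drives every stream (per-bird and per-vessel
substreams by fixed offsets), so identical configurations reproduce
byte-identical datasets.

Conventions worth knowing when extending the package: distances are
spherical haversine with R = 6371 km (ellipsoidal accuracy is irrelevant at
250-m bins); all timestamps are UTC internally with a fixed UTC+2 offset
applied only for diel summaries and day boundaries; distance bins and the
pairing window are half-open; the breakpoint validation boundary is closed;
chi-square tests are uncorrected by default; and every stochastic routine
takes an explicit seed and restores the caller's RNG state.

## Known limitations

- Sitting bouts shorter than the GPS interval are partly misclassified
  because interpolated ground speed cannot resolve them.
- The interaction distance is identified at bin resolution; under VMS
  interpolation error of a few hundred metres the measured sitting profile
  is a smeared step, and the estimator's spread across replicate studies is
  of the order of one bin.
- Mixed-model denominator degrees of freedom are a convention; for
  publication-grade inference on real data, Satterthwaite or
  Kenward-Roger approximations should be preferred.
- Events are bird x vessel: a bird attending two nearby vessels at once
  yields two events by design.
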