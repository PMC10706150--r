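---
title: "Methods: evaluating low-cost PM2.5 sensors by collocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating low-cost PM2.5 sensors by collocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacolloc)
```

## The measurement problem

Optical particle counters estimate PM2.5 mass from laser scattering. Their
raw output depends on the aerosol's size distribution and refractive index,
so a unit deployed in a woodsmoke-dominated airshed needs either a
site-appropriate conversion or a per-unit calibration against reference
equipment. `pacolloc` implements the full evaluation chain — conversion,
quality control, aggregation, comparison — together with a synthetic-data
generator rich enough to exercise every stage.

## Conversions

Four routes from raw sensor output to PM2.5 are provided.

**Linear cf1 calibration.** `pm25 = intercept + slope * cf1`, with per-unit
coefficients obtained by regressing reference PM2.5 on the unit's raw `cf1`
during a co-location period. The packaged table
(`inst/extdata/calibrations.yaml`) holds eight deployed units; units without
a fitted row fall back, with a warning, to the generic woodsmoke conversion
`(0.53, 0.55)` used for uncalibrated sensors. Slopes near 0.5–0.6 reflect
the cf1 algorithm's overestimation of woodsmoke mass.

**ALT-3.4.** The count-based conversion
`pm25 = 3.4 (0.00030418 N1 + 0.0018512 N2 + 0.02069706 N3)` differences the
cumulative >0.3, >0.5, >1, >2.5 µm channels into bin counts and sums
water-density sphere masses scaled by an empirical factor of 3.4. It needs
no per-unit calibration, which is its practical appeal. The derived
sub-micron fraction `P1` is a useful aerosol-type diagnostic: woodsmoke sits
near 1, dusty aerosols lower. Counts are accepted as reals because averaged
records carry fractional counts; the only validity requirement is
monotonicity of the cumulative channels. The mass ratio between 2.5 µm and
1 µm spheres, `(2.5)^3 ≈ 16`, explains why a small number of coarse
particles dominates `W2.5` and why optical algorithms tuned to combustion
aerosols underestimate dusty ones.

**US EPA conversion.** `pm25 = 0.524 cf1 − 0.0862 RH + 5.75`. The RH terms
form an RH-dependent intercept (−2.87 µg/m³ at 100% RH, zero near 66.7%,
+2.91 at 33%); the function validates RH into [0, 100] and permits negative
outputs. Inside the pipeline, per-channel values are floored at zero before
fusion, which requires non-negative channel means.

**Nephelometer.** `pm25 = 0.53 + 22.186 * neph` converts integrating
nephelometer scattering to woodsmoke PM2.5. The coefficient is bound to the
instrument's reported scattering unit (Aurora 1000G); the package treats the
input as an opaque instrument value and applies the affine map, negative
readings included.

Out of scope by design: the quadratic bushfire extension for
`cf1 > 343 µg/m³` and the dust correction keyed to the 0.3 µm/5 µm count
ratio. Both address aerosols outside the woodsmoke regime this package
targets.

## Dual-channel quality control

Each unit carries two identical laser sensors sampling the same air, so
hardware faults appear as A/B discordance. With hourly channel means
`L ≤ H`, `AD = H − L`, `m = (L + H)/2`, an hour is *discordant* when
`AD > 10 µg/m³` **and** `AD > 0.5 m`. Discordant hours are fused as
`wt1·L + (1 − wt1)·H`, `wt1 = 0.5 (1 + min(1, AD/m))`: the weight on the low
channel rises continuously with the relative disagreement and saturates at 1
when `AD ≥ m`, at which point the high channel is ignored. The saturation
point makes the rule continuous there, and the fused value always lies
within `[L, H]`.

Three conventions the rule itself does not fix:

- *Concordant hours* use the plain two-channel mean.
- *"50% of the mean"* is read as `AD > 0.5 m` — consistent with the
  saturation point being "the difference exceeds their mean".
- *Single-channel hours* are retained, flagged discordant with `wt_low = 1`,
  rather than dropped: completeness matters under a 23-hour daily rule, and
  the flag preserves the audit trail. `discordance_rate()` counts only
  two-channel disagreements, so retained single-channel hours do not inflate
  the reported rate (observed in the field at about 1.25 h per year per
  sensor).

A division by `m = 0` cannot occur (discordance requires `AD > 10` with
non-negative channels) but is guarded with an explicit error anyway.
Thresholds are arguments with the field-standard defaults.

## Temporal aggregation

2-minute records are assigned to the clock hour containing their interval
midpoint, matching how reference hourly data are stamped: a record from
23:58:59 to 00:00:59 belongs to the 23:00 hour. Assignment partitions the
records, so none is counted twice. Days need at least 23 valid hourly values
— stricter than the common 18-hour convention, because in woodsmoke towns
an 18-hour average missing the evening peak is not comparable to one missing
midday hours. Exclusion windows are inclusive of both end dates (the source
records give only month ranges, so whole months are excluded); the defaults
are the Black Summer bushfire period (2019-11-01 to 2020-01-31 — the
narrower of the two stated ranges, matching the period the headline
statistics exclude) and January–May 2022, a window of suspect reference
data. Both are user-editable. All timestamps are local standard time; the
readers reject zone designators rather than silently converting, and
negative reference values are retained (real FDMS TEOMs report them).

## Collocation statistics

On paired complete, non-excluded daily averages: Pearson `r`;
`RMSE = sqrt(mean((PA − ref)²))`; the reduced-major-axis slope
`sign(r)·sd(ref)/sd(PA)`, appropriate when both variables carry error; and
the OLS fit oriented reference-on-candidate (`ref = slope·PA + intercept`)
throughout, so RMA and OLS slopes are directly comparable. OLS attenuates
relative to RMA whenever `r² < 1`. At least 3 pairs and non-zero variance
are required.

For the correlation's standard error no formula is stated in the source
material; the package uses `sqrt((1 − r²)/(n − 2))`, the standard
large-sample form. Published tables from comparable analyses are consistent
with this at n ≈ 600 but print larger SEs at n ≈ 189 than this formula
gives (0.03 vs ≈ 0.02), suggesting a different convention there; the
discrepancy is flagged rather than reverse-engineered.

`residual_diagnostics()` correlates daily residuals (`ref − PA`) with the
sensor-derived P1 and with the reference PM2.5/PM10 ratio. A negative
residual-vs-ratio correlation is the signature of dust-day underestimation:
when coarse particles dominate, the optical estimate falls short.

## The synthetic site

The generator exists so the pipeline is testable end to end without
downloads. What it emulates, and what it does not:

- **Truth process** (minute scale):
  `(baseline + peak · diurnal(t) · season(t)) · exp(z_t)` with a
  wrapped-Gaussian diurnal kernel centred at 21:00 (σ = 3 h) — evening wood
  heating — a winter-high cosine seasonal factor centred on day-of-year 183
  (Southern Hemisphere), and AR(1) lognormal noise (`sdlog` 0.25, per-minute
  ρ = 0.9, about a 10-minute correlation scale). Defaults: baseline
  3 µg/m³, evening peak 25 µg/m³, seasonal amplitude 0.8 — winter evenings
  reach tens of µg/m³ while summer afternoons sit near the baseline, the
  regime such towns show. The functional forms are this package's choice;
  nothing in the source material prescribes them, and all are
  config-exposed.
- **Sub-micron fraction** interpolates between 0.97 (mid-winter, nearly
  pure smoke) and 0.75 (mid-summer, more dust) along the same seasonal
  cosine.
- **Sensors**: per channel, `cf1` inverts the unit's calibration with
  multiplicative Gaussian noise (cv 0.05 per 2-min record) and is floored at
  zero, so calibration recovers the observed mass in expectation.
  Size-channel counts are synthesised by solving the three-weight linear
  system so that `alt34()` equals the channel's mass exactly with the target
  P1, splitting sub-micron counts N1:N2 = 9:1 (a smoke-like ratio; the split
  is a free parameter because one fraction cannot pin down two bins).
  One-channel spikes (Poisson, default 1.25/yr — the observed field rate —
  of +50 µg/m³ for one hour) exercise the QC rule. The option
  `pa_coarse_response < 1` attenuates the sensor's response to 1–2.5 µm
  mass, injecting the dust-day bias for diagnostic tests; the default of 1
  keeps the sensors unbiased.
- **Reference**: hourly values average the truth over the five 6-minute
  measurement windows of the FDMS 12-minute cycle (phase configurable), so
  within-hour variation produces genuine duty-cycle error; Gaussian noise
  (sd 2 µg/m³, an instrument-grade 1-h precision) is added and negatives
  retained. PM10 adds a summer-high coarse component (≈ 4.5 µg/m³ mean). A
  nephelometer stream inverts the woodsmoke relationship plus noise.
- **Seeding**: one seed; each instrument stream derives a sub-seed from a
  stable hash of its name, so adding a unit never perturbs existing streams,
  and identical configs are bit-identical.

What passing tests on this generator show: the pipeline's algebra,
plumbing, determinism and error handling are correct, and parameters
injected under the generator's assumptions are recovered. What they do not
show: performance on real aerosols — the generator has no humidity response,
no calibration drift, no fog droplets, no wind-blown dust episodes
uncorrelated with season, and its reference shares the truth process with
the sensors, which real co-located instruments only approximate.

## Numerical and design choices

- Problem sizes in the tests are one simulated winter (92 days at minute
  resolution, ≈ 2200 collocated hours) for calibration recovery and 1–2
  simulated years elsewhere; these give sampling error comfortably inside
  the tested tolerances.
- Calibration recovery regresses hourly reference on hourly-averaged raw
  cf1 (the reference's native resolution, and the same regression that
  produced the packaged calibrations' form).
- `cfa` (the alternative proprietary conversion) is parsed, carried and
  written back but never used in computation, keeping file round-trips
  lossless.
- The unknown-unit fallback warns rather than errors: deployments routinely
  include unfitted units, and the default conversion is the documented
  practice for them.
- Zero-variance inputs, empty day intersections, and sub-3-day comparisons
  raise classed errors; `run_pipeline()` skips (with a classed warning)
  reporting periods that contain no overlapping days and errors only if none
  remains.
- The CLI consolidates fuse/aggregate/compare/report into one `compare`
  subcommand: the intermediate stages are exported functions, and splitting
  them across processes would only add CSV round-trips.

## Known limitations

The generator's counts are exactly consistent with its cf1 stream, so the
woodsmoke and ALT-3.4 conversions coincide on synthetic data; on real data
they differ at low concentrations, where cf1 truncates small values to zero.
The RMA estimator is the two-variable special case; no allowance is made
for autocorrelation in daily series when quoting `r_se`. Exposure mapping
(kriging, population weighting) and health-cost estimation are out of scope.
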