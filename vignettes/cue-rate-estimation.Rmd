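---
title: "Cue-rate estimation for migrating gray whales: models, corrections, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cue-rate estimation for migrating gray whales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalecues)
```

## The estimation problem

Migrating gray whales pass a shore station along a narrow corridor over the
continental shelf. Three sensors watch the same water: visual observers
(daytime, good conditions only), a four-hydrophone array recording the M3
migratory call continuously, and an infrared camera that sees the thermal
signature of blows day and night. The visual census yields modelled daily
abundances with 95% credibility intervals; the autonomous sensors yield cue
counts. The conversion factor between the two is the cue rate,

$$\hat r(t) = \frac{\hat N_C(t)}{\hat N_W(t)\,\hat P_{SA}\,\bar t_{SA}},$$

and its inverse turns cue counts into whale numbers for periods without
visual effort. Everything in this package serves one of the four factors:

* $\hat N_C(t)$ — detected cues corrected to produced cues
  (`correct_call_count()`, `correct_call_count_by_minute()`,
  `correct_blow_count()`);
* $\hat N_W(t)$ — supplied daily abundances (an input, not re-modelled
  here);
* $\hat P_{SA}$ — the proportion of whales inside a sensor's search area,
  from the visually observed offshore distribution
  (`build_offshore_distribution()`, `proportion_in_interval()`);
* $\bar t_{SA}$ — mean transit time through the search area
  (`acoustic_transit_time()`, `camera_transit_time()`).

## Corrections and their assumptions

**Probability of localization.** A call is usable only if localized, which
requires adequate SNR on all four hydrophones. `localization_field()` holds
source-level realizations (100 draws in the standard configuration),
per-cell per-hydrophone transmission loss, and per-minute noise;
`probability_of_localization()` scores each grid cell by the fraction of
realizations whose minimum across-array SNR exceeds 0.5 dB, and averages
cells without weighting (the search area is treated as homogeneous in whale
density for this average). Transmission loss is pluggable;
`tl_spherical_spreading()` (20 log10 r) is the default, a deliberate
simplification — the machinery being exercised is the Monte Carlo and the
effort rule, not ocean acoustics. Minutes with mean probability below 0.5
are declared off-effort (`apply_effort_rule()`): their calls are dropped
and they accumulate into $P_{NE}$ instead of being corrected by an
unreliable factor.

Daily corrected call counts can be formed two ways: one day-level division
by the mean on-effort probability (`correct_call_count()`), or per-minute
division then summation (`correct_call_count_by_minute()`). The per-minute
form is the package's reference: it weights each call by the conditions
under which it was detectable, and reduces exactly to the day-level form
when the probability is constant. Both are exported because the day-level
form is what the printed summary constants support.

**Direction correction.** The visual abundance model counts southbound
whales only, so calls from northbound or milling whales are false alarms
for the rate's denominator. $\hat c_N$ is the group-size-weighted
complement of the southbound share, each pod represented by its last
recorded direction and group size (`southbound_proportion()`). This assumes
southbound and northbound whales call at the same rate.

**Camera effective range.** The camera cannot reliably resolve blows at
long range. Rather than a detection-function fit, the effective maximum
range is estimated by comparing cumulative detection and sighting counts
versus range (`effective_detection_range()`): where the camera sees
everything, the detections-per-sighting cumulative ratio is flat; beyond
its effective range the ratio falls. The change point maximizes the SSE
improvement of a continuous two-segment piecewise-linear fit of the ratio
over a single line, with two numerical guards: the innermost points are
excluded until at least 10 sightings (or 5% of them) have accumulated,
because the ratio there is a quotient of small counts, and an improvement
below 20% (or an exactly linear ratio) is declared degenerate, returning
the maximum observed range — the correct answer when detections simply
mirror sightings. On simulated data with a known 2.1 km truncation against
sightings uniform to 3 km, the estimate lands within 10% of truth in at
least 95% of replicates (tested at 100 replicates, 500 sightings each).
Within the effective window (default (500, 2100] m; the near cutoff
excludes the vanishingly narrow wedge close to shore) detection probability
is taken as 1, the same assumption a human review of good-condition video
supports. The band is half-open on both ends — strictly greater than the
near cutoff, less than or equal to the far edge.

**Day/night symmetry.** `day_night_comparison()` returns the share of
detections inside the visual watch window (07:30–16:30 by default, 9 of 24
hours) and a two-sided Wilcoxon rank-sum test of hourly counts, exact by
enumeration when both groups are small (at most 20 per group) and tie-free,
normal approximation with continuity and tie correction otherwise. Fully
tied samples are reported as p = 1: ranks carry no information there. Under
equal detectability the day share should be near 9/24.

**Visibility.** Infrared visibility is scored as the population variance of
per-row mean grey intensity of a frame (`visibility_metric()`): a sharp
sea/sky contrast gives high variance, haze flattens it. The score is
translation-invariant by construction.

## Geometry

Camera georeferencing follows single-station photogrammetry on a spherical
earth. A pixel row below the calibrated horizon row maps to a depression
angle by linear interpolation of the 5° vertical field of view; adding the
horizon dip $\arccos(R/(R+h))$ gives the depression below the local
horizontal, and the surface distance solves
$\tan\beta = ((R+h) - R\cos\gamma)/(R\sin\gamma)$ for the central angle
$\gamma$, found by root bracketing on $(0, \gamma_{horizon}]$ where the
solution is unique. No refraction model is applied; an effective-radius
multiplier (default 1) is exposed for users who want the standard k-factor
correction. No lens-distortion model: the field of view is 6.2° wide, where
a linear pixel-angle map is adequate. The horizon row is a required
per-deployment calibration — whether the original analysis referenced the
image top edge or a measured horizon is not recoverable, and a calibration
input covers both. At the camera height of 28.1 m the spherical solution
departs from the flat-earth distance $h/\tan\beta$ by 0.28% at 1 km and
1.1% at 2 km, so the curvature term matters precisely over the camera's
usable band.

Azimuths interpolate linearly between the calibrated true bearings of the
image edges (exact at both endpoints; columns run 0 to width − 1 with
integer pixel centres). Positions come from the great-circle forward
solution (via `geosphere`, spherical radius), whose inverse round-trips to
under 1 m within 10 km.

Transit times: the array is crossed along ~2,280 m at the mean measured
swimming speed of 1.6 m/s (23.75 min); the camera wedge is crossed along an
arc $2\pi r \cdot 6.2/360$, averaged over the sighting-weighted offshore
distribution before dividing by speed.

## The calling-rate model and extrapolation

Daily calling rates rise over the southbound migration. `fit_power_model()`
fits $f(x) = a x^b + c$ (x = day index, origin x = 1 at the season start,
1 December) by Levenberg–Marquardt least squares. Because $a$ spans many
orders of magnitude, the optimizer works in $(\log a, b, c)$ — the optimum
is unchanged but the conditioning is dramatically better; on noise-free
curve samples the generating coefficients are recovered to well beyond four
significant figures. Starting values are data-driven ($c_0$ = minimum rate;
$a_0, b_0$ from a log-log regression of the excess), with a sloped-restart
fallback for the near-constant case where $x^b$ at $b \approx 0$ is
collinear with the intercept. The coefficient covariance is mapped back to
$(a, b, c)$ by the delta method.

`prediction_interval()` produces the pointwise (non-simultaneous) interval
$f(x) \pm t_{dof}\sqrt{\hat\sigma^2 + g^T V g}$ by first-order
linearization, with the gradient $g = (x^b, a x^b \log x, 1)$. The interval
is for a *new daily rate observation*, which is what the back-estimation
divides by; simulation at 100 noisy replicates confirms coverage consistent
with the nominal 95% within binomial error. Lower bounds are floored at
zero rather than enforced by constrained fitting — the fit itself is
unconstrained and the floor only affects reporting. Extrapolating left of
the fitted days toward x = 1 the interval widens monotonically, which is
the honest statement that December rates are unobserved.

`whales_from_cues()` and `december_backestimate()` invert the identity. Two
protections matter near zero: a rate floor (default $10^{-6}$
calls/whale/day) below which estimates are capped and flagged rather than
allowed to diverge, and the convention that the *upper* rate bound gives
the *minimum* whale count, so the defensible direction of the uncertainty
is always available even when the lower bound is degenerate. December days
are assumed to have no northbound or milling component ($c_N = 0$): no
sightings exist then to estimate one, and the northbound migration has not
begun. The fit is unweighted; daily abundance uncertainty enters only
through the reported rate bounds, matching how the credibility intervals
are used elsewhere (no uncertainty is propagated from $P_{SA}$,
$\bar t_{SA}$, or the counts themselves).

## The synthetic-data generator

`simulation_config()` / `simulate_tracks()` / `simulate_calls()` /
`simulate_blows()` / `simulate_detections()` emulate the statistical
structure the analysis assumes, so every downstream stage is testable
without the field data:

* straight shore-parallel tracks at a constant 1.6 m/s and a fixed offshore
  distance — the same idealization behind every transit-time formula;
* offshore distances from a configurable distribution; the default uniform
  mixture spans 185 m–9.4 km (the span of real sightings) with weights
  0.13/0.53/0.34 on (185, 500], (500, 2100], (2100, 9400] m, placing 53% of
  whales in the camera band and about two-thirds inshore of the array's
  offshore edge;
* calls as a per-whale Poisson process at the configured daily rate while
  the whale is in the corridor (the emission process is not otherwise
  constrained by observation; Poisson is the minimal choice given only a
  rate);
* blows as a renewal process: 2–4 blows per surfacing bout, 20–30 s apart,
  then a 3–4 min dive, all drawn uniformly and independently within those
  ranges; the long dive starts from the bout's last blow. The degenerate
  midpoint cycle (3 blows, 25 s, 210 s) gives the closed-form rate
  3/260 s⁻¹ ≈ 41.5 blows/hour, inside the 27–67.2 blows/whale/hour span
  reported from field observation;
* detection as domain clipping (range window, camera wedge) × effort
  minutes × an independent Bernoulli draw; camera records carry pixel
  coordinates produced by inverting the geometry mappings, so
  georeferencing can be tested round-trip;
* one global seed with per-stage substreams derived deterministically from
  it: every operation is bit-reproducible and stages can be re-run
  independently.

What the generator does *not* emulate — curved or milling tracks, pods,
within-day calling-rate structure (no diel pattern is imposed by default
because none is established; the effort machinery supports one), weather-
and range-dependent detection of real sensors, and spatially correlated
noise — bounds what green tests mean: they validate the estimators under
the model's own assumptions, not the sensors' field performance.

## Problem sizes and numerical choices

The test suite and workflow run at deliberately modest scale, chosen as the
smallest sizes at which the statistical assertions have power: binomial and
Poisson oracles use 3-standard-error bands at 2,000–10,000 whales;
end-to-end rate recovery uses ~10,000 whale-hours of corridor residence;
change-point recovery uses 500 sightings × 100 replicates;
prediction-interval coverage uses 100 replicate fits. Root-finding
tolerances are 1e-13 (geometry) and the LM fit runs to ftol = ptol = 1e-15.
Half-open range bands, strict condition cutoffs (Beaufort and visibility
strictly less than 5), and last-recorded pod attributes are applied exactly
as stated throughout.

## Known limitations

* The visual abundance model is an input; its poor fit in some seasons
  propagates directly into the rate bounds, which is why bounds here use
  only the abundance credibility interval.
* $\hat P_{SA}$ from sightings is group-size weighted; a pod-count
  weighting would differ slightly (the choice is not settled by the
  available summaries, and group-size weighting matches how whales, not
  pods, enter the abundance).
* The transmission-loss default is generic spreading; site-specific
  propagation changes $\hat P_L$ levels (not the machinery).
* Seasonal average rates count each whale on both passes (southbound +
  northbound), which is required for season-long call totals; daily rates
  count southbound only, matching the southbound-only abundance. Mixing the
  two conventions is the easiest way to misuse the package.
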