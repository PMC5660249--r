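---
title: "Modelling wind selectivity of trans-Gulf songbird migrants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wind selectivity of trans-Gulf songbird migrants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gulfcross)
```

`gulfcross` models the decision problem of a nocturnal songbird migrant
staged on the northern Gulf of Mexico coast: whether the winds of a given
night reward stopping over, departing across the water, or waiting. This
vignette is the methods account — the models, their assumptions, the
tunable parameters and why their defaults are what they are, the numerical
choices, and what the synthetic data can and cannot tell you.

## The wind model and its conventions

Winds live on a `WindGrid`: a regular space–time lattice of eastward (`u`)
and northward (`v`) components at a single nominal altitude, with 3-hourly
snapshots and a fixed horizontal spacing (default 32 km), the shape of a
regional reanalysis product. All directions in the package are degrees
clockwise from geographic north in the *toward* convention — the direction
the air moves, which is also the direction a supported bird moves — and all
angle arithmetic is mod 360. A zero wind vector is assigned direction 0 by
convention; nothing downstream depends on it because speed multiplies every
cosine.

The quantity of interest everywhere is the *tailwind* (wind profit) along a
reference travel direction $\alpha_1$ for wind toward $\alpha_2$ at speed
$w$:

$$\mathrm{tailwind} = \cos(\alpha_1 - \alpha_2)\, w
 = u \sin\alpha_1 + v \cos\alpha_1 .$$

Winds with tailwind strictly greater than 0 m/s are *supportive*; 0 or
below is a headwind. That threshold is a single shared constant used by the
nightly summaries and the forecasting-consistency metrics alike.

Because a bird's endogenous goal direction is unknown, tailwind is averaged
over five candidate departure directions spanning the plausible trans-Gulf
bearings (120°, 150°, 180°, 210°, 240°). The nightly mean further averages
over the five 3-hourly UTC instants 00:00–12:00 (local evening to morning
at the study longitude), giving 25 values per night; the nightly *slope* is
the ordinary-least-squares slope of the five per-instant direction means
against hours elapsed (0, 3, …, 12). OLS was chosen because only "a slope"
is scientifically required; it is exact, closed-form, and testable.

**Night labelling.** A night is named by its local *evening* date: night
$D$ runs from the evening of $D$ to the morning of $D+1$. Its five UTC wind
samples therefore fall on calendar date $D+1$ (the site is ~6 h west of
Greenwich), its departure instant is the evening civil twilight of local
date $D$, and its stopover flag corresponds to captures on the morning of
$D+1$. One convention, used by every module.

## Interpolation

Winds at arbitrary points and times come from inverse-distance weighting of
the four surrounding grid nodes, separately for `u` and `v`, with weights
$1/d^p$ on great-circle distances in metres — degree-space distances would
distort with latitude. The exponent $p$ defaults to 1 and is exposed as a
configuration knob because the method is conventionally specified only as
"inverse-distance"; nothing in the package's conclusions is sensitive to
$p$ at grid scales. Queries that coincide with a node return the stored
value exactly (a guard triggers below 1 µm). Time is handled by linear
interpolation between the two bracketing 3-h snapshots, which nightly
summaries never exercise (they sample exactly on snapshots) but twilight
launches and hourly track steps do. Queries outside the grid raise a typed
extent condition that the trajectory module records as `domain_exit`.

## Civil twilight

Departure is anchored at evening civil twilight — the instant the sun
reaches 6° below the horizon — computed from a standard low-accuracy solar
position approximation (Fourier expansions for declination and the equation
of time, then the hour-angle equation at zenith 96°). The approximation is
good to a few minutes at mid latitudes, far finer than the 3-h wind
resolution; observed departure times can be supplied as overrides. Polar
edge cases are out of scope (`|lat| < 60` enforced).

## The forward trajectory model

Each night, five virtual migrants launch from the origin (default
30.2° N, 88.0° W, a coastal staging peninsula) at civil twilight, one per
candidate direction. The behavioural assumptions are deliberately rigid,
matching what is known of this species' flight: a *constant heading* solved
once from the wind at launch, a *constant airspeed* of 10 m/s, and a
nominal 1-km flight altitude (metadata only — a single wind level is used,
defensible because reanalysis winds at neighbouring levels are strongly
correlated).

The heading comes from the wind triangle: with crosswind $c = w
\sin(\alpha_2 - \alpha_1)$ perpendicular to the target track $\alpha_1$,

$$h = \alpha_1 - \arcsin(c / a),$$

which makes the air vector plus wind vector point along $\alpha_1$. When
$|c| > a$ the track is unflyable and the track is flagged infeasible
(typed condition; the night is marked invalid if any of its five tracks is
infeasible).

Each one-hour step samples the wind at the step's *start* position and time
(an explicit choice — winds update hourly, and sampling at the start keeps
the first step's wind identical to the heading-solution wind), vector-sums
air and wind to get groundspeed and track direction, and advances along the
loxodrome (constant-bearing rhumb line) on a sphere of radius 6371 km.
Spherical rather than ellipsoidal geodesy keeps the formulas transparent;
the difference is metres over a 1600-km crossing, far below the 32-km wind
resolution. Point $i$ of a track records the state at the start of step
$i$, so a track that lands on its first advance carries exactly one wind
sample.

Termination is exact and threefold: `reached_land` when at least one of
the four raster nodes nearest the new position is land; `max_steps` after
45 one-hour steps (ten hours beyond the longest observed crossing);
`domain_exit` when the position or next sample time leaves the wind or
mask data. The two data-limit reasons are recorded distinctly because they
mean different things scientifically.

Two per-night summaries feed the analyses: the *departure tailwind* (mean
first-step tailwind across the five tracks — local wind profit at launch)
and the *Gulf mean tailwind* (mean over tracks of each track's per-step
mean — wind profit integrated over the crossing).

## Selectivity statistics

**Logistic models.** Stopover (or departure) is regressed on period,
tailwind, and their interaction via maximum likelihood
(`stats::glm`, binomial logit). Period is the season half split at the
*median capture date* — computed from captures, not nights — dummy coded
early = 0, late = 1, with the split date itself going to "late". Year is
accepted as an optional covariate but the headline model is
`response ~ period * tailwind`. Model fit is the deviance difference
against the intercept-only model on its χ² reference; per-term tests are
Wald z. Variance inflation factors follow the textbook definition — each
design column regressed on the others, $\mathrm{VIF} = 1/(1 - R^2)$ —
computed directly from the design matrix because the conventional
`car::vif` refuses interaction models (the two agree exactly on
interaction-free linear models, which a test verifies). Perfect separation
aborts the fit with a diagnostic condition rather than returning divergent
estimates. Nights with a closed station the next morning or missing wind
are dropped before every analysis.

**Monte-Carlo mean tests.** Whether selected nights (arrivals, departures)
had unusual winds is tested by resampling: each of `nSims` (default 1000)
draws picks the observed number of nights *without replacement* from all
available nights and records the mean statistic. The one-tailed p-value is
$(r+1)/(n+1)$ with $r$ the count of draws at least as extreme as the
observed mean; the tail is chosen by the sign of (observed − mean of
draws), and ties count toward $r$ — the conservative reading. Sampling
without replacement reflects that a "random assignment of arrival nights"
is a subset of real nights. All draws flow through one shared
night-selection routine, so the windowed test, the forecasting suite, and
the plain mean test are exactly identical when their designs coincide
under the same seed — a property the tests assert literally.

One calibration subtlety is worth stating because it is easy to misread:
with the tail picked adaptively from the data, the null rejection rate at
nominal $\alpha$ is $2\lfloor\alpha(n+1)\rfloor/(n+1) \approx 2\alpha$
(both tails can trigger), while a pre-specified tail rejects at
$\approx \alpha$. The acceptance checks verify both derived rates under
exchangeable synthetic winds.

**Windowed Monte-Carlo.** To place arrival choices in their seasonal
context, the mean tailwind is computed at offsets −10…+10 nights around
the focal arrival nights, with the focal set restricted to a 10 Sep–21 Oct
window so every offset night is equally represented within the recorded
season. One random draw of pseudo-arrival nights per simulation serves all
21 offsets, so the expected curve inherits the season's changing wind
availability. Offset dates that fall before the recorded season (only
possible at the window edge) drop out of both observed and expected means
symmetrically, preserving exchangeability.

**Annual regression.** Capture rate per net-hour against annual mean
tailwind by ordinary least squares with the F-test and adjusted $R^2$.

## Forecasting metrics

Per track, *supportiveness consistency* compares each step's supportiveness
with the first step's: the proportion of matching steps, and
`hoursToChange`, the length of the initial matching run (the first
differing step minus one; `NA` if none differs — the three fields are
mutually redundant by construction and validated as such). Cross-track
aggregation to a night is not uniquely defined, so both readings are
exposed: the arithmetic mean of per-track proportions (headline) and the
fraction of tracks consistent throughout. The departure–Gulf relation is a
Pearson correlation plus the paired mean improvement; the three
forecasting Monte-Carlo tests apply the shared mean-test machinery to Gulf
tailwinds, the Gulf-minus-departure difference, and mean consistency, with
departure nights as the selected set (sub-seeds seed, seed+1, seed+2).

## The synthetic-data generator

The generator exists so that every analysis above can be exercised, seeded
and tested end to end. It emulates the *structure* of reanalysis winds,
not their physics: each component is a constant mean flow plus an anomaly
field built from white noise smoothed by a Gaussian kernel (width
`spatialCorrKm`) and evolved as a stationary AR(1) across the 3-h
snapshots. The smoothed field is renormalized cell by cell (including grid
edges) so the marginal anomaly SD is exactly `anomalySd`, and the lag-1
autocorrelation of every cell series is exactly `temporalAr1`. `u` and `v`
anomalies are independent — none of the analyses uses u–v
cross-correlation.

Defaults are fixed once from the study conditions: domain 15–32° N,
75–100° W; season 1 Sep–31 Oct; 3-h / 32-km resolution; mean flow 2 m/s
toward 231° (the observed mean coastal wind direction); anomaly SD 4 m/s,
putting nightly tailwind SDs in the observed 3.6–4.4 m/s band. The
reanalysis's true space–time covariance is not characterized in the source
material, so `spatialCorrKm = 300` and `temporalAr1 = 0.7` are free knobs
set to values a synoptic meteorologist would call plausible for
subtropical marine boundary flow (several-hundred-km weather structures
persisting across nights); they are documented, not claimed to match the
reanalysis.

The land–water mask is rasterized from a *stylized, hand-drawn* coastline
polygon shipped as a plain-text fixture (`gulf_coast_synthetic.csv` —
synthetic by name and by nature): mainland plus Cuba, coarse on purpose,
giving tracks realistic landfall geometry without pretending to be a real
shoreline. A cell is land iff its center falls inside a polygon, so
rasterization is idempotent and traversal-order free.

Bird-nights are drawn from the same logistic structure the selectivity
models fit: stopover from the night-mean tailwind, departure from the
twilight tailwind, each with its own coefficient set defaulting to the
fitted magnitudes of the study system (e.g. intercept −0.22, tailwind
0.17 for arrival), plus a station-closure probability of 78/1281 matching
the observed closure rate. This makes parameter recovery a meaningful
test: refitting simulated seasons recovers the generating coefficients
within two standard errors.

**What passing tests do and do not show.** The synthetic fields are
Gaussian, stationary, and front-free; real Gulf winds have fronts,
tropical storms, diurnal structure, and u–v coupling. Green tests
demonstrate that the *machinery* — interpolation, geometry, resampling,
model fitting — is correct and calibrated, not that the ecological effect
sizes of the real system are reproduced. Real-data quantities that depend
on the actual reanalysis and banding records (observed wind climatologies,
fitted field coefficients, the r = 0.88 departure–Gulf correlation) are
deliberately not asserted anywhere; the synthetic-season pipeline reports
its own analogues of these numbers without comparing them.

## Numerical choices and degenerate inputs

* Earth radius 6371 km everywhere; kilometres per degree latitude
  $= 6371\pi/180 \approx 111.195$.
* IDW node-hit guard at $10^{-6}$ m; extent violations are typed
  conditions, never silent NAs.
* Zero wind: direction 0 by convention; zero groundspeed steps leave the
  position unchanged (the rhumb formula is skipped rather than evaluated
  at zero distance).
* Rhumb steps near due-east/west use the $\cos\varphi$ limit when the
  stretched-latitude increment falls below $10^{-12}$.
* `mcMeanTest` requires a nonempty selection no larger than the available
  pool; a selection equal to the pool gives every draw tied and p = 1.
* All-equal values give p = 1 by the tie rule, the defined degenerate
  outcome.
* Logistic fits abort (typed condition) on separation or non-convergence
  instead of returning meaningless standard errors.
* Generator determinism is bitwise: same config and seed, identical grids
  and identical flags.

## Problem sizes

The shipped tests and the results script run entirely on synthetic data at
sizes chosen for tight oracle comparisons: oracle agreement on 1000
randomized queries; trajectory closed forms over full 45-step tracks;
exhaustive-subset exactness at ≤12 nights (≤495 subsets) against
10⁴ Monte-Carlo draws; logistic recovery at 2000 nights and null
calibration over 500 refits of 400 nights; windowed-Monte-Carlo
calibration over 200 synthetic seasons at 200 draws each; and a 30-night
synthetic season through the full wind→trajectory→statistics pipeline.

## Known limitations

* CSV is the interchange format for grids, masks and night records;
  NetCDF containers are not read or written.
* The generator's spatial kernel is isotropic in grid-index space; at the
  default domain the lon/lat cell aspect varies mildly with latitude, so
  physical anisotropy of a few percent is possible.
* Single wind level: altitude selection behaviour cannot be studied.
* The stylized coastline is not a shoreline; landfall positions are
  qualitative.
* Twilight accuracy degrades poleward of ~60°, which is outside the
  supported domain.
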