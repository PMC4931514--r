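---
title: "Methods: use-availability habitat selection for open-space foraging bats around wind turbines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: use-availability habitat selection for open-space foraging bats around wind turbines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Open-space foraging bats (the common noctule, *Nyctalus noctula*, is the
type case) hunt in uncluttered airspace tens to hundreds of metres above
ground — the same height stratum swept by wind-turbine rotors. Given
high-resolution GPS telemetry (30-s fixes over the night, from one hour
before sunset to one hour after sunrise) around a roost in a farmland
landscape, the analysis asks three questions:

1. **Movement**: how long and far are nightly trips, how fast and high do
   the animals fly over each land-use class, and do the sexes (confounded
   with season by the recording schedule — males tracked in early summer,
   females in midsummer) differ?
2. **Selection**: which habitats are used more or less than expected given
   what was *available* to each animal on that trip, and how do distances
   to turbines and to linear structures modulate presence?
3. **Exposure**: what fraction of open-habitat flight heights falls inside
   the rotor-swept zone of the local turbine fleet?

## The availability null: constrained correlated random walks

Use-availability designs need a null that respects movement constraints.
For each observed trip we build five correlated random walks (CRWs) with
the same number of relocations:

* the walk starts at the roost, with a uniformly random initial heading
  (the data do not constrain the starting direction, so the least
  informative choice is used);
* each step draws a step length and a turning angle *independently, with
  replacement*, from the trip's own empirical pools (so the null preserves
  the animal's speed and tortuosity spectrum but randomises where it goes);
* every vertex must stay inside the trip's minimum convex polygon (MCP)
  dilated by half the square root of the MCP area. For a convex polygon the
  dilated area is exactly `A + P*d + pi*d^2`, which is also how
  `buffer_region()` reports it; containment is tested against the exact
  dilation (distance to the hull at most `d`), not the discretised boundary.

Whole-walk rejection is the default constraint semantics (`mode =
"reject"`): a completed walk with any vertex outside is discarded, which
leaves the joint step/turn distribution untouched apart from the
containment conditioning. Because nearly straight trips (thin MCPs with
narrow turning-angle pools) can make acceptance rare, after `max_attempts`
rejections the generator falls back to per-step constraint with whole-walk
restarts; `mode = "stepwise"` requests that behaviour outright. Both modes
are exposed because the constraint semantics of the original method are
ambiguous; they differ only near the region boundary.

Each replicate `r` of a trip is seeded with `seed + r`, so a (trip, seed)
pair reproduces bit-identically.

## The selection model

Bat fixes (presence = 1) and CRW vertices (pseudo-absence = 0, five walks
per trip, hence a 5:1 ratio) are annotated with the land-use class of
their location, the distance to the nearest turbine base and the distance
to the nearest linear structure (roads, treelines, hedgerows and similar,
merged into one layer). Distances enter linearly after centring/scaling;
a collinearity screen (Pearson `|r| < 0.25` among the continuous
covariates) halts the analysis unless explicitly overridden.

`fit_rsf()` fits, via `lme4::glmer` (Laplace approximation),

```
logit P(presence) = land_class + dist_turbine + dist_linear
                    (+ each term x sex)
                    + b_individual + b_trip(individual)
```

with both random intercepts Normal(0, sigma^2), trips nested within
individuals. The land-use reference level is conventional cropland (the
dominant class). Sex and season are a single confounded factor, called
"sex". Candidate fixed structures are ranked by AIC (`select_by_aic()`),
ties broken by parsimony. `variance_structure = "none"` pins both
variances at zero, in which case the marginal likelihood reduces exactly
to the Bernoulli likelihood of the fixed effects; the package maximises
that directly (BFGS with analytic gradient on internally whitened
columns), and the tests verify coefficient agreement with an ordinary
logistic regression to 1e-4.

### The 0.5 benchmark

Displays read selection against 0.5: above 0.5, use exceeds availability.
Because the design is imbalanced 1:5, a raw fitted probability of an
uninformative model would sit at 1/6, not 1/2. `effect_curve()` therefore
subtracts the fixed offset `logit(pi0)` (`pi0` = presence fraction) from
the linear predictor before transforming, so an intercept-only model is
exactly 0.5 everywhere. This offset correction is this package's explicit
choice for handling the imbalance. Other covariates are held at their mean
raw values (mapped through whatever standardization the fit used — curves
are invariant to the standardization constants), random effects at zero,
and 95% intervals are Wald on the logit scale, transformed, so bounds stay
inside (0, 1).

## Exact small-sample tests

With eight animals, between-sex comparisons need exact tests.
`mann_whitney_exact()` builds the full null distribution of U by the
Gaussian-binomial counting recursion (enumeration over group assignments
of midranks under ties) and reports `U = max(U1, U2)` with the two-sided p
doubling the smaller tail, capped at 1 — the convention under which
complete separation at n = 3 vs 5 prints `U = 15, p = 0.036, n = 8`. The
alternative "sum of both tails" convention is available
(`p_convention = "tail_sum"`); the two differ only under asymmetric
(tied) nulls. `wilcoxon_signed_rank_exact()` drops zero differences,
ranks the absolute differences (midranks under ties), and enumerates the
2^n sign patterns by a subset-sum convolution (doubled midranks are
integers). Beyond n1*n2 = 1e6 (Mann-Whitney) or 25 pairs (signed rank) a
flagged normal approximation with tie correction is used.

## Exposure to the rotor-swept zone

A turbine with hub height `H` and rotor radius `R` sweeps `[H - R, H + R]`.
`blade_density()` counts, on a 1-m grid, the turbines sweeping each
height; `peak_blade_band()` reports the maximal contiguous run at peak
density. `band_occupancy()` reports the unrounded percentage of
open-habitat fixes (conventional cropland, organic cropland, grassland —
the classes over which device heights are trusted and rotors stand) inside
a closed band, plus a nearest-integer label (halves round away from zero).
`height_interval()` gives the central 95% interval
`[q(0.025), q(0.975)]` with interpolated quantiles; the lower bound is
clamped at zero when all heights are non-negative, since height above
ground cannot be negative.

## Geometry, projection and solar events

All distances are planar metres in a local azimuthal-equidistant frame
centred on the roost, built from geodesic distance and bearing
(`geosphere`); at the 20-km scale of the study pairwise planar distances
agree with WGS84 geodesics within 0.5% (tested). Point-in-polygon,
point-to-segment distance, convex hulls (`grDevices::chull` with a
counter-clockwise convention) and convex Minkowski dilation are implemented
in the package and validated against brute-force oracles, including an
independent gift-wrapping hull. Land-use lookups resolve shared polygon
edges to the polygon listed first in layer order (documented, tested);
points outside the extent are annotated with the nearest class and a
warning, never dropped.

Sunset and sunrise use the NOAA solar-calculator equations with standard
refraction (sun centre at -0.833 degrees), iterated once at the
provisional event time; latitudes at or beyond 66.5 degrees are rejected.
The test suite checks 30 dates at the study site against an independent
solar-position implementation (the PSA algorithm with bisection), with
agreement well within 2 minutes.

## Trip segmentation choices

* **Gap tolerance**: 150 s (five nominal 30-s intervals). The cut between
  "continuous" runs is not prescribed by the data; this keeps a track
  contiguous through isolated GPS dropouts while splitting genuine
  interruptions.
* **Windows**: an evening trip starts between one hour before sunset and
  solar midnight; a morning trip ends within 180 min before sunrise (a
  margin around the observed "ended ~25 min before sunrise" behaviour).
  Runs matching neither are excluded, with a logged count.
* **Per-class speeds** attach each consecutive-fix speed (straight-line
  displacement over elapsed time — a minimum-speed estimate) to the
  land-use class of the segment midpoint.
* Missing heights are excluded pairwise, never imputed.

## The synthetic study

`gen_landscape()`/`gen_tracks()` generate the full study from known
parameters, so every stage is testable without field data. The landscape
is a seeded nearest-nucleus mosaic of 400 patches over 10 x 10 km (mean
field ~25 ha, labelled to hit the seven-class target proportions within
3 percentage points), dominated by conventional cropland (55%), with ~20
small scattered water bodies (5%), settlements placed adjacent to water,
turbine rows (100-m hubs, 33-m rotors, so the fleet sweeps 67-133 m) on
cropland, linear features crossing the extent, and the roost in a small
forest patch at the projection origin.

Movement is *endpoint step selection*: each 30-s step proposes 20
candidates (gamma step lengths — male mean ~186 m per step, i.e. ~6.2 m/s,
female ~126 m, ~4.2 m/s; wrapped-normal turns with mean resultant length
0.8) and picks one with probability proportional to
`exp(beta . covariates(endpoint))`. The default coefficients encode the
scenario's structure: water strongly preferred (+2), grassland, urban and
organic cropland mildly preferred (+0.5), conventional cropland and forest
avoided (-1), females drawn toward turbines (-0.3 per km of distance) and
males away (+0.3), both sexes drawn to linear structures. Departures are
Normal(24, 15) min after sunset; a homing penalty on roost distance over
the final 15% of fixes returns the bat. Heights are class- and
sex-specific lognormals (open-habitat medians ~62 m female, ~31 m male).

The generator is *deliberately not* the fitted model: the analysis
compares use against CRW availability, while the generator selects step
endpoints. Because of that intentional mismatch (and the spatial
autocorrelation a patch mosaic induces), acceptance is recovery of signs
and orderings — water above 0.5, conventional cropland below 0.5, water >
grassland > cropland — across seeded replicates, not equality of
coefficients. The end-to-end checks evaluate the ordering on the
main-effects candidate fit, which gives one probability per class. What
passing these tests shows is that the pipeline recovers a known preference
structure under realistic mosaic geometry; what it cannot show is
calibration against real GPS error, device-dependent height bias, or
behavioural states (commuting vs foraging), none of which the generator
emulates.

## Problem sizes and numerical choices

The packaged study conditions are 8 individuals (5 "male" early summer, 3
"female" midsummer), one night each, 120-fix evening trips (one hour at
30 s) and a few 30-fix morning trips, five CRWs per trip — about 6300
model rows per run; the replicate suites use 50 seeds for variance
recovery (30 individuals x 200 rows each) and 25 seeds end to end.
Variance recovery of a true sigma^2 = 1 is judged inside [0.5, 1.8], the
interval a Laplace binomial fit of this size supports. Other numerical
choices: convergence of the pinned-variance optimiser at relative
tolerance 1e-14 with one restart; CRW `max_attempts = 10000`,
`step_retries = 1000`, 200 whole-walk restarts; the correlation screen
halts at `|r| >= 0.25` (synthetic landscapes can legitimately exceed this
between the two distance covariates, so the pipeline exposes
`cor_override`); rank-deficient interaction columns (a class unvisited by
one sex) are dropped by `lme4` and the effect machinery tolerates their
absence.

## Known limitations

* Heights are taken as the supplied `height_agl`; whether a device
  reports true height above ground is outside the package's control.
* The CRW null conditions on the *observed* trip's pools and MCP; trips
  that barely left the roost produce degenerate regions, and nearly
  straight trips force the per-step fallback more often.
* Organic cropland in the emulated landscape (and in the motivating
  system) is rare and spatially clustered; its selection estimate is
  correspondingly unstable, and no de-clustering is attempted.
* No GPS-error smoothing, no behavioural-state classification, no
  collision-risk mechanics (rotor speed, avoidance) — exposure is overlap
  only.
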