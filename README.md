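# batselect

Habitat selection of GPS-tracked open-space foraging bats in wind-energy
landscapes.

Open-space foragers such as the common noctule (*Nyctalus noctula*) hunt
high above ground, in the height stratum swept by wind-turbine rotors.
`batselect` implements the full analysis chain for high-resolution GPS
telemetry of such bats around a roost:

* **Trips** — ingest 30-s fix tables, project them into a local planar
  frame centred on the roost, compute sunset/sunrise (NOAA equations),
  segment fixes into evening and morning trips, and summarise movement
  (duration, cumulative distance, roost distances, per-class minimum
  speeds, open-habitat flight heights, emergence and return offsets).
* **Availability null** — for each trip, five roost-anchored correlated
  random walks (CRWs) resampling the trip's own step lengths and turning
  angles, confined to the trip's minimum convex polygon buffered by half
  the square root of its area.
* **Selection model** — a use-availability binomial GLMM (logit link,
  `lme4`), presence vs CRW pseudo-absence with trips nested within
  individuals as random intercepts:

  `logit P(presence) = land_class + dist_turbine + dist_linear (+ term:sex) + b_ind + b_trip(ind)`

  with a Pearson `|r| < 0.25` collinearity screen, AIC model ranking, and
  effect curves on the probability scale where 0.5 means "use equals
  availability" (the 1:5 design imbalance is removed by a `logit(pi0)`
  offset).
* **Exact rank tests** — Mann-Whitney U and Wilcoxon signed-rank with
  fully enumerated null distributions for small samples, reported in the
  field's style (`U = 15, p = 0.036, n = 8`).
* **Rotor exposure** — per-height blade density of the turbine fleet, the
  peak rotor band, band occupancy of open-habitat flight heights and
  central 95% height intervals.
* **Synthetic studies** — a seeded generator for farmland mosaics
  (cropland-dominated, scattered ponds, settlements near water, turbine
  rows, linear features) and habitat-biased bat tracks with known
  selection coefficients, so the whole pipeline is testable end to end.

## Worked example

```r
library(batselect)

# exact Mann-Whitney: cropland flight speeds, 3 females vs 5 males
mann_whitney_exact(c(6.2, 5.1, 8.0), c(4.2, 4.0, 4.4, 3.9, 4.5))
#> U = 15, p = 0.036, n = 8

# solar events at the roost for one tracking night
solar_events("2014-07-01", lon = 14.048, lat = 53.373)
#> $sunset   2014-07-01 19:35:00 UTC
#> $sunrise  2014-07-02 02:40:39 UTC

# a full synthetic study: simulate, segment, CRW null, fit, exposure
cfg <- pipeline_config(seed = 7, cor_override = TRUE,
                       scenario = scenario_config(fixes_per_trip = 80))
out <- run_pipeline(cfg, "run7")

out$aic
#>              model  k    loglik      aic converged delta_aic
#> 1 sex_interactions 20 -1857.857 3755.714      TRUE   0.00000
#> 2             main 11 -1882.776 3787.551      TRUE  31.83696

effect_curve(out$fits$main, "land_class")[, c("value", "estimate")]
#>                   class    p   lo   hi
#> 1 conventional_cropland 0.44 0.39 0.49
#> 3             grassland 0.64 0.57 0.70
#> 6            open_water 0.80 0.73 0.85
#> ... (7 classes)

out$exposure[[length(out$exposure)]]
#> Exposure (all): 494 open-habitat fixes
#>   rotor band: 21% (n = 106/494)
#>   central 95% heights: 12.6-98.3 m; quartiles 27.2/44.3/63.2 m
```

The AIC table says the sex-interaction structure explains the simulated
data better than main effects alone (the generator gave the sexes opposite
turbine responses). The class curve reads against 0.5: open water (0.80)
is used far above its availability, grassland moderately so (0.64), and
conventional cropland below availability (0.44) — the preference ordering
the generator embedded. The exposure block reports how many open-habitat
fixes fell inside the fleet's rotor-swept band (67–133 m for 100-m hubs
with 33-m rotors).

A shell driver with the same stages is installed at
`inst/scripts/batselect-pipeline.R`:

```sh
Rscript inst/scripts/batselect-pipeline.R --config cfg.yml --out outdir --stages all
```

Each run writes CSV/GeoJSON/JSON artifacts plus `manifest.json` with MD5
checksums, parameters and the seed; identical configurations reproduce
byte-identical outputs.

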