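# windwue

Attribution of grassland ecosystem water-use efficiency change to
wind-speed trends.

## What this is for

Ecosystem water-use efficiency — WUE = GPP/ET, in g C per kg H2O — is the
carbon an ecosystem gains per unit of water it loses. Over grasslands,
near-surface wind speed regulates WUE through boundary-layer conductance
and soil-moisture feedbacks: slower wind suppresses evapotranspiration,
retains soil moisture and supports carbon uptake. Because the land wind
record is triphasic (multi-decadal "stilling" to ~2010, a reversal, then a
projected renewed decline), the wind contribution to WUE trends is itself
time-dependent.

`windwue` is for researchers who want to quantify that contribution with a
fully testable pipeline. It provides:

* **PCR sensitivity estimation** — per pixel or flux site, WUE and seven
  collinear drivers (wind, air temperature, air pressure, precipitation,
  shortwave radiation, VPD, CO2) are z-score standardized, decomposed into
  principal components, the components capturing >85% of variance are
  retained, and the regression coefficients are back-transformed to
  original units:
  `beta_j = (s_y / s_xj) * sum_k L_jk * beta*_k`. The wind entry is
  dWUE/dWind in g C kg-1 H2O (m s-1)-1. With all components retained this
  equals direct least squares exactly (a property the tests assert to
  1e-8).
* **Monte Carlo uncertainty** — a seeded year-bootstrap (1000 replicates)
  rerunning the full PCR, reported as SD/|mean| of the wind coefficient.
* **Wind/SM interaction** — the ratio Wind/SM as an eighth predictor,
  capturing the amplification of the wind effect under dry soils.
* **Trend and turning-point analysis** — OLS trends per decade with
  significance, negative-pixel fractions, a start-year trend scan
  (2010-2080, end fixed 2100) and an exhaustive continuous segmented
  regression, plus the three-phase partition of the wind record.
* **Contribution decomposition** — per-driver induced WUE change
  `beta_j x slope_j x (n-1)` and fractional contributions of each driver
  to the total WUE change, with explicit residual.
* **A synthetic-data module** — gridded drivers with known sensitivities,
  realistic cross-correlations (wind-pressure anticorrelation, a single
  global CO2 series), a triphasic wind trajectory, and daily flux-site
  tables with built-in degenerate cases for the screening rules
  (ET < 0.05 mm day-1 days, WUE outliers above the per-site 99th
  percentile, stations with incomplete monthly coverage).

Everything is seeded: identical configuration and seed give bit-identical
results.

## Worked example

```r
library(windwue)

cfg <- run_config(seed = 1L, grid_shape = c(10, 10), target_r2 = 0.85)
report <- run_pipeline(cfg)
print(report)
#> <run_report>
#>   grid 10 x 10, 118 years, 100/100 pixels kept
#>   median dWUE/dWind = -0.1217 (100.0% of pixels negative), mean R2 = 0.784
#>   hist wind trend -0.0831 m/s per decade (-2.48%/decade); turning points: scan 2080, segmented 2030
#>   wind-induced WUE change (median) 0.02619 g C kg-1 H2O; wind share 20.8%
```

Reading this output: the synthetic world was generated with a true wind
sensitivity of -0.13 g C kg-1 H2O per m s-1 and a wind trajectory declining
-0.0072 m s-1 yr-1 until 2010, recovering until 2028, then declining again.
The per-pixel PCR recovers a spatial median of -0.1217 (the ~6% shortfall
is the expected shrinkage from retaining components to 85% variance), with
the correct sign everywhere. The historical wind trend over 1983-2010 is
-0.083 m s-1 per decade (-2.48% of the 3.35 m s-1 mean) for this
realization. The segmented detector places the second turning point at
2030, two years from the true 2028; the start-year scan lands far from it
(2080) — on piecewise-linear series with noise its objective is flat past
the true break, a documented limitation (see the methods vignette), which
is why the pipeline partitions phases at the segmented estimate.
Multiplying the median sensitivity by the 1983-2014 wind trend gives a
wind-induced WUE increase of 0.026 g C kg-1 H2O, 20.8% of the total WUE
change — second only to CO2 in this world, with VPD contributing
negatively.

## The analysis workflow

The `analysis/` directory holds the staged workflow, each script a thin
narrative driver over the package functions, writing text tables under
`results/`:

```sh
Rscript analysis/01_simulate.R      --seed 1   # synthetic world + truth sidecar
Rscript analysis/02_screen_filter.R            # site/station screening report
Rscript analysis/03_sensitivity.R   --seed 1   # PCR maps, bootstrap, interaction
Rscript analysis/04_trend_turning.R --seed 1   # trends, turning points, phases
Rscript analysis/05_attribution.R   --seed 1   # contribution decomposition
```

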