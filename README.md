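# bombusim

Process-based simulation of wild central-place-foraging pollinators —
parameterized for common early-active bumble bees — on categorical
land-use rasters, for assessing how agri-environment measures (sown
flower strips, widened grassy field margins) affect pollinator
populations and the pollination services they deliver.

Statistical pollination-service maps score habitat by distance to
nesting sites only. `bombusim` instead models the mechanisms that make
management outcomes non-obvious: bees preferentially forage on more
rewarding flowers (so new floral resources can *steal* visits from
crops and wildflowers that bloom at the same time — apparent
competition), and populations grow across seasons in response to
accumulated resources (so the same measure can depress services in
year one and raise them five years later). It is aimed at landscape
ecologists and ecosystem-service modellers who want to compare
management scenarios on real or synthetic landscape rasters.

## The model

A season has two floral periods (period 1: the mass-flowering-crop
bloom, e.g. oilseed rape; period 2: the rest of the summer). On a 25-m
raster, floral value is `F_k = coverage × attractiveness` per cell and
period, and nesting capacity is `NQ × n_max × cell area` colonies per
cell, both derived from a land-use lookup table with uncultivated
field margins mixed in proportionally to each cell's field-edge
length.

**Foraging (visitation).** The rate at which cell *i* is visited by
bees nesting in cells *j* is

    V_i = Σ_j X_j · F_i e^(−d_ij/β) / Σ_q F_q e^(−d_qj/β) · ρ_F^d_ij

an exponential-kernel allocation (mean distance β = 530 m, truncated
at its 99th percentile) of each cell's foragers over the flowers in
reach, weighted by floral value. Queens forage in period 1 (one per
colony), a fraction `p_w` of workers in period 2.

**Resources and colony growth.** Each nest collects resources
proportional to the kernel-weighted mean floral value around it
(flowers are not depleted). Workers then queens are produced through a
saturating lognormal-CDF production function `G(R; a, b)` with median
`a` and variance `b`: `W = Q · w_max · G(R₁; a_w, b_w)` and
`Q_E = Q · q_max · G(R₂; a_q, b_q)`.

**Between seasons.** New queens disperse with a longer kernel
(β̃ = 1000 m), choose destinations weighted by nesting capacity,
expected arrivals are truncated at each cell's capacity
(density-dependent mortality), and realized colony numbers are Poisson
draws — the model's only stochastic step.

All spatial sums are exact truncated-kernel convolutions evaluated by
FFT, verified against brute-force double loops in the test suite.

## Worked example

```r
library(bombusim)
lut <- default_resource_lookup()
params <- reference_params()

spec <- landscape_spec(extent = 5000, mean_field_size = 10,
                       osr_target = 0.15, seminatural_frac = 0.08, seed = 31)
rotation <- generate_landscape(spec)
landscape_covariates(rotation[[1]], buffer_radius = 2000)
#>  osr_area_ha edge_area_ha
#>      140.875       19.878

baseline <- run_simulation(rotation, lut, params, scenario(),
                           n_cycles = 1, burn_in_cycles = 1,
                           seed = 1, buffer_radius = 2000)
round(baseline[c(1, 4, 7), 1:5], 3)
#>   year colonies_per_ha mean_workers_per_colony mean_queens_per_colony visit_per_flower_p1
#> 1    1           0.889                 545.153                 39.744               5.380
#> 4    4           0.851                 586.855                 41.415               5.263
#> 7    7           0.812                 574.200                 43.354               4.665
```

The 7-year rotation holds about 0.85 colonies/ha after burn-in
(roughly 140 ha of oilseed rape and 20 ha of field-edge habitat inside
the 2-km analysis buffer), with ~575 workers and ~41 new queens per
colony. Sowing flower strips on 1.25% of the agricultural land:

```r
strips <- run_simulation(rotation, lut, params, scenario(strips = TRUE),
                         n_cycles = 1, burn_in_cycles = 1,
                         seed = 1, buffer_radius = 2000)
round(log_response_ratio(strips$colonies_per_ha, baseline$colonies_per_ha), 3)
#> [1] 0.000 0.090 0.344 0.396 0.387 0.433 0.415
```

The log10 response ratio of population size is zero in the treatment's
first year (colonies were founded before the strips were sown), then
builds up over several seasons to about +0.4 (a ~2.6-fold increase) —
the characteristic time lag of floral-resource interventions.

A command-line front end with `simulate`, `scenario-compare` and
`make-landscapes` subcommands is installed under
`system.file("cli", "bombusim", package = "bombusim")`.

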