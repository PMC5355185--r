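---
title: "bombusim: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bombusim: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bombusim` simulates populations of central-place-foraging bees on
categorical land-use rasters and maps the flower visitation they
provide. This vignette is the package's own account of the model: what
is computed, which knobs matter, which design decisions were open and
how they were settled, and what the packaged synthetic experiments do
and do not demonstrate.

## The seasonal model

The season is split into two floral periods: period 1 is the bloom of
the early mass-flowering crop (oilseed rape, OSR), period 2 the rest
of the activity season. The yearly cycle, driven by `run_season()`, is:

1. **Queen foraging (period 1).** Each colony is founded by one queen
   who forages herself: the forager field is the queen raster itself.
   `visitation_rates()` allocates the foragers of every source cell
   *j* over the flowering cells *i* within reach, in proportion to
   floral value discounted by distance,
   $$V_i = \sum_j X_j\,
     \frac{F_i\,e^{-d_{ij}/\beta}}{\sum_q F_q\,e^{-d_{qj}/\beta}}\,
     \rho_F^{\,d_{ij}},$$
   with Euclidean center-to-center distances and the kernel truncated
   at its 99th percentile. The normalization encodes "full
   information": a farther cell with better flowers can receive more
   visits than a near, poor one. With per-meter survival
   $\rho_F = 1$, every forager lands somewhere: total visits equal
   total foragers.
2. **Resource collection.** `resources_per_nest()` gives each nest the
   kernel-weighted mean floral value around it times its foragers per
   nest. Flowers are not depleted, so nests do not compete for them —
   visitation *dilution* (more flowers sharing the same foragers) is
   the only competitive mechanism in the model.
3. **Worker production.** $W = Q\,w_{\max}\,G(R_1; a_w, b_w)$, where
   $G$ is the cumulative distribution function of a lognormal with
   median $a$ (resources at half-maximal production) and variance $b$
   (steepness). A fraction $p_w$ of workers forage in period 2.
4. **Queen production.** Period-2 collection feeds
   $Q_E = Q\,q_{\max}\,G(R_2; a_q, b_q)$. With the default parameters
   the queen curve is effectively a threshold at $R_2 \approx a_q$:
   its standard deviation is ~1% of its median, so colonies either
   produce close to $q_{\max}$ queens or almost none. This makes
   late-season floral resources the decisive, limiting resource.
5. **Overwinter dispersal and settlement.**
   `overwinter_disperse()` spreads new queens with a longer kernel
   ($\tilde\beta$), weighting destination cells and normalizing per
   source. Expected arrivals are truncated at the cell's nesting
   capacity *first*, and realized colony numbers are then Poisson
   draws — the two-step order matters, and the Poisson draw is the
   only stochastic, integer-valued step of the year. Workers and
   queens stay continuous within the season.

## Parameters

| name | meaning | unit | default |
|------|---------|------|---------|
| `n_max` | colonies in a cell of nesting quality 1 | nests/ha | 19.6 |
| `beta` | mean foraging distance | m | 530 |
| `beta_nest` | mean nest-searching dispersal distance | m | 1000 |
| `a_w`, `b_w` | worker growth median / steepness | resource units | 100, 200 |
| `a_q`, `b_q` | queen growth median / steepness | resource units | 15000, 30000 |
| `w_max` | max workers per queen | — | 600 |
| `q_max` | max new queens per colony | — | 160 |
| `p_w` | fraction of workers foraging | — | 0.5 |
| `rho_F`, `rho_N` | per-meter flight survival (foraging / dispersal) | — | 1, 1 |
| `kernel_quantile` | kernel truncation quantile | — | 0.99 |

The steepness parameters are tied to twice their medians by default.
`a_q` is a calibration constant rather than a measured quantity: it
sets where the queen-production threshold sits relative to the floral
value scale of the lookup table (below).

## From land use to resources

Each cell mixes its land-use patch with the grassy margin habitat
along its field-block edges: the margin fraction is
$f = \min(1,\ \text{edge length} \times \text{margin width} /
\text{cell area})$, and floral value, coverage and nesting quality are
area-weighted means of patch and margin values. This linear mixing
conserves habitat area — widening margins from 2.4 m to 4.8 m
displaces crop rather than creating area from nothing — and yields the
two directional effects widening should have: nesting capacity never
decreases (margins have maximal nesting quality) and floral value next
to a mass-flowering crop never increases (margins have very low floral
value). `n_max` is given per hectare and converted to the 0.0625-ha
cell exactly once, in `build_nesting_raster()`.

The packaged lookup table (`default_resource_lookup()`) is
**synthetic**: a stand-in for an expert scoring of southern Swedish
land uses, honouring the qualitative structure — OSR as a large pure
period-1 pulse; cereal near-zero in both periods; ley moderate early,
poor late (cut before late bloom); seminatural grassland the best
wild-flower and nesting habitat; margins maximum nesting quality at
negligible floral value; flower strips high period-2 coverage at
maximum attractiveness but poor nesting quality. Its absolute scale
was calibrated once against the fixed growth parameters so that
baseline populations persist without saturating: worker growth must be
viable away from OSR (kernel-mean period-1 floral value near `a_w`),
while period-2 resources cross the queen threshold only near
concentrations of seminatural habitat. Users supplying their own
tables should preserve that relationship between floral-value scale
and `a_w`, `a_q`.

## Management interventions

* **Field margins**: the margin width used in resource building
  switches from 2.4 m to 4.8 m.
* **Flower strips**: 25 × 50 m strips on ~1.25% of the agricultural
  land, re-placed every year (arable land is plowed), implemented by
  converting the two cells to the `flower_strip` land use for the
  whole season. A strip sown on an OSR field therefore removes that
  cell's period-1 flowers, and crop area shrinks by the strip area —
  interventions consume land, they do not conjure it.
* Placement is a deterministic greedy stand-in for an optimized
  scheme: cell pairs are ranked by kernel-weighted nesting capacity
  minus kernel-weighted existing period-2 floral supply (each term
  standardized by its landscape mean — the raw quantities differ by
  orders of magnitude and an unstandardized difference degenerates to
  "avoid flowers", placing strips in empty plains), ties broken by
  row-major order, overlaps forbidden. The score function is a
  pluggable argument, and the same placement is used in every scenario
  of a landscape-year, so treatments differ only in what is sown, not
  where.

Because placement is scenario-independent, the response series reports
period-2 per-flower visitation *excluding would-be strip cells* in
every scenario, so the apparent-competition metric compares identical
cell sets between baseline and treatment.

## Synthetic landscapes

`generate_landscape()` emulates intensively farmed mosaic landscapes:
rectangular field blocks from recursive random splitting (mean block
area set by `mean_field_size`, which also controls edge density and
hence structural heterogeneity), permanent covers assigned to whole
blocks — seminatural grassland *clustered* around a few foci, as
pastures and stream corridors are in real landscapes — and a cyclic
rotation that moves OSR between arable blocks (never the same block
two years running) while holding its landscape share near
`osr_target`. `sample_landscape_specs()` draws OSR targets and field
sizes independently, giving uncorrelated gradients; at the default
10-km extent with a 3-km buffer the default ranges span roughly
14–323 ha of OSR and 17–78 ha of edge habitat.

What the generator does **not** emulate: real geography (roads,
settlements, soil gradients), within-block heterogeneity, non-square
field geometry, and empirically elicited resource scores. Passing
tests on these landscapes shows the model mechanisms behave correctly
and produce the expected emergent patterns under controlled
conditions; it does not validate predictions for any real landscape.

## Study conditions for the packaged experiments

The scenario experiments (`scenario_compare()`, the acceptance script,
and the emergent-behavior tests) run with `reference_params()`:
default parameters except `rho_N = 0.997` per meter (about 5% of
queens survive a 1-km flight). The reason is structural: a colony can
produce up to `q_max = 160` queens while a cell holds at most ~1.2
colonies, so with lossless dispersal any self-sustaining population
floods every cell within kernel reach and equilibrates at full nesting
saturation — and a saturated baseline cannot respond to interventions
at all. The queen-production median being a fixed constant, en-route
queen mortality is the model's own mechanism for keeping landscapes
populated but not saturated, and is applied uniformly across all
scenarios. `bb_params()` itself keeps `rho_N = 1` so the mechanism is
opt-in.

Problem sizes were chosen as the smallest that exhibit the
core/periphery population structure the mechanisms need: 5-km rasters
(200 × 200 cells) with a 2-km analysis buffer, ensembles of 12–20
landscapes, one 7-year baseline burn-in cycle carried over into 2
treated cycles (population state is continuous across the burn-in
boundary), and 35-year runs for stationarity checks. First-year colony
counts are identical across scenarios sharing a seed — settlement
happens at season's end — so population-size comparisons drop year 1.

## Numerical choices

* Every spatial sum (visitation numerator and normalization, per-nest
  resources, settlement) is a convolution with a radially symmetric
  truncated kernel, evaluated exactly by zero-padded FFT (5-smooth
  padded sizes, kernel FFTs cached). Truncation is applied
  consistently in numerators and denominators, and the normalization
  runs over the raster cells inside the truncation disc — including
  the per-nest resource denominator $\sum_j e^{-d_{ij}/\beta}$, whose
  summation set is read as the same cells as its numerator.
* Normalization sums below $10^{-10}$ of their landscape maximum are
  treated as exactly zero: FFT round-off otherwise leaves $\sim
  10^{-13}$ residues that division inflates into phantom foragers or
  settlers on sparse landscapes. A source with a zero sum simply has
  nothing in reach: its foragers visit nothing, its queens are lost
  (counted, not an error).
* The lognormal parameter conversion is closed-form: with median $a$
  and variance $b$, $\sigma^2 = \log\big((1 + \sqrt{1 + 4b/a^2})/2\big)$
  (the variance identity is quadratic in $e^{\sigma^2}$), which makes
  $G(a; a, b) = 1/2$ exact.
* The dispersal destination weight is nesting capacity by default:
  the literal alternative — weighting by the current queen
  distribution — is circular at settlement time (the queens being
  placed are the next year's distribution) and strands queens wherever
  the population is momentarily absent. Both modes are implemented
  (`dispersal_weight` in `bb_params()`).
* Queens whose entire reachable destination weight is zero die; they
  are not redistributed.
* Determinism: a single integer seed drives initialization and every
  Poisson draw; identical configurations give byte-identical response
  CSVs. Landscape generation uses its own seed and restores the
  caller's RNG state.

## Limitations

Floral resources are not depleted, so exploitation competition among
bees is absent (apparent competition through visitation dilution is
the only competitive pathway). Two floral periods limit temporal
resolution. One species at a time; no males, no within-colony caste
dynamics, no explicit winter mortality beyond dispersal losses and
settlement truncation. The lookup table is a calibrated synthetic
stand-in, so quantitative outputs are illustrative; the robust
products are directional and relative effects — strips versus margins,
early versus late season, short versus long term.
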