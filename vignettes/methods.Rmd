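---
title: "Methods: heat-envelope screening for dryland species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-envelope screening for dryland species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The screening rests on a *demonstrated tolerance* argument. If a species
persists today in parts of its range where the maximum temperature of the
warmest month (BIO5) reaches some value, it has demonstrated tolerance of
that value. The attained range of BIO5 over a species' range polygon is
its **heat envelope** `[env_min, env_max]`; the upper bound is the
**thermal maximum** (TM). Envelopes are computed for two epochs:

* **historical** range — the (larger) range formerly occupied; its TM is
  the strongest tolerance evidence available;
* **current** range — the present, typically contracted and nested,
  range; its TM is the conservative, directly demonstrated tolerance.

For a future climate scenario, the **overlap** is the percentage of
current-range cells whose projected BIO5 stays at or below the envelope
TM (`mode = "upper"`, the default; `mode = "two_sided"` additionally
requires values at or above `env_min`). Overlaps are computed for every
member of a scenario ensemble (by default 5 GCMs x 3 SSPs = 15 futures)
and summarised by the ensemble mean and standard error `SE = sd /
sqrt(k)`.

### Risk tiers

With a threshold of 50% (strict inequalities throughout):

* `low` — `mean − SE > 50` against **both** the current and the
  historical envelope;
* `moderate` — `mean − SE > 50` against the historical envelope only;
* `high` — otherwise.

Subtracting one SE is a deliberate safety margin: ensemble spread can
only *raise* a species' tier, never lower it. The `upgraded` flag records
when the raw means alone would have placed the species in a lower tier.

### Refugia

`refugia_map()` benchmarks every historical-range cell against the
historical TM: cells at or below it under **all** scenarios are candidate
refugia; `some` and `none` grade the remainder; cells outside the polygon
are `outside` (integer codes 1/2/3/0 in the exported ASCII grid).

### Translocation sites

Each site is sampled at the grid cell containing its coordinates. Across
the ensemble, the site's **mild / mean / extreme** projections are the
minimum, mean and maximum of the per-scenario values, each compared
(strictly) against the current and historical TMs, giving six exceedance
flags and per-species percentage summaries.

### Trait associations

Risk tiers are cross-tabulated against categorical traits (taxonomic
order, IUCN listing) and tested with Pearson's chi-squared test *without*
continuity correction. Continuous traits are compared across tiers with
the tie-corrected Kruskal–Wallis test, followed by Dunn's post-hoc z
tests,

`z_ij = (Rbar_i − Rbar_j) / sqrt[(N(N+1)/12 − ΣT/(12(N−1))) (1/n_i + 1/n_j)]`

with `T = t³ − t` summed over tied values, and optional Holm or
Bonferroni adjustment. `review_tally()` summarises study effort per tier
and tests for research bias with the same Kruskal–Wallis machinery.
Reported percentages use round-half-away-from-zero, matching common
reporting practice rather than R's banker's rounding.

## Data formats and geometry

The package deliberately avoids the GDAL-based spatial stack. Rasters are
ESRI ASCII grids (`.asc`, plain text, optional `scale`/`offset` for
integer-packed sources); range polygons are GeoJSON FeatureCollections
(one `historical` and one `current` feature per `species_id`); everything
else is CSV/YAML. Geometry is implemented exactly:

* point-in-polygon by even-odd ray casting (validated in the test suite
  against the independent implementation in `mgcv::in.out`);
* polygon area by a vertical trapezoid sweep over the edge arrangement,
  exact for simple rings and assigning self-intersecting rings their
  filled (even-odd) area;
* zonal extraction by the **cell-center** rule by default, with an
  `all_touched` rule (boundary cell traversal) to rescue sub-cell ranges;
  optional `cos(latitude)` area weighting.

Extraction order is deterministic (row-major), and the whole pipeline is
deterministic given a configuration: reruns produce byte-identical
artifacts (this is asserted in the test suite).

## The synthetic generator

The generators double as the package's validation instrument: they
construct worlds whose correct answers are known by construction, and the
test suite requires the full geometric pipeline to recover them.

* `make_baseline()` — a north–south BIO5 gradient
  (`base + gradient * (y − ymin)` plus optional noise). Defaults (120 x
  120 cells, 0.25° resolution, base 18 °C, gradient 0.9 °C/°) span
  roughly 18–45 °C, a realistic dryland BIO5 range. The problem size is
  the package's own choice: large enough that per-cell errors cannot hide
  in tolerances, small enough for fast tests.
* `make_scenarios()` — warming fields added to the baseline, with
  per-scenario mean warming spread over `delta_range = c(1, 4)` °C by
  default, bracketing mid-century ensemble spread across SSPs; spatial
  patterns `uniform`, `gradient` or `patchy`, each normalised so the
  spatial mean equals the scenario's warming level.
* `make_species()` — ranges are unions of grid cells selected by baseline
  value: the historical range occupies the value window
  `[TM_hist − hist_width, TM_hist]` (anchored near a high quantile so a
  hotter margin exists), and the current range a nested, column-restricted
  window below `TM_hist − Δ`. The current width and Δ are solved by
  bisection against *exactly computed* ensemble overlaps, so the achieved
  mean overlaps land on the targets and the classification rule provably
  recovers the intended tier; construction fails loudly rather than
  silently mislabel.

  A design choice worth noting: the overlap targets and `delta_tm`
  over-determine the construction, so when overlap targets are supplied
  (or implied by `target_tier`) they govern and Δ is *derived*;
  `delta_tm` is honoured directly only when both overlap targets are
  `NULL`.
* `make_sites()` — sites at historical-range cell centers chosen by
  value quantile (low quantiles are cool candidate refugia), with true
  exceedance flags recorded by direct arithmetic on the grids.
* `simulate_bundle()` — a complete on-disk input bundle (grids, ranges,
  sites, traits, study counts, config, ground truth) in the interchange
  formats `run_screening()` consumes.

### Generator scope

The generator is a validation and demonstration instrument, not a climate
model: warming fields are stylised, ranges are value-window cell unions
rather than realistic range shapes, and traits are drawn independently of
tier (except study counts, which mirror the research-bias structure).
Conclusions about real species require real BIO5 surfaces and mapped
ranges in the supported formats.

## Numerical choices

* Strict `>` comparisons at the 50% threshold and for TM exceedance; ties
  fail the criterion (the conservative direction).
* Ensemble SE is `sd/sqrt(k)` over the `k` scenario overlaps; with one
  scenario the SE is 0.
* Envelopes are attained extrema of extracted cell values — no density
  fitting enters classification; kernel density estimates
  (`export_density_profile()`) are for visualisation only and are
  renormalised to unit integral.
* ASCII grids are written with full precision (15 significant digits), so
  write/read round trips are exact for the values used here.
* Bisection in `make_species()` uses 30 iterations over two passes;
  achieved overlaps are recomputed exactly afterwards and the
  classification re-checked.

## Limitations

* BIO5 exposure only: no physiology, behaviour, microclimate buffering,
  water balance, or biotic interactions.
* Demonstrated tolerance is a lower bound on true tolerance; equally, TM
  attained at a range margin may reflect a sink, not persistence.
* The even-odd union in `poly_union()` is exact only for disjoint parts
  (the case produced by the range constructions here).
* The cell-center rule under-samples ranges smaller than a cell; use
  `inclusion_rule = "all_touched"` for such species.
* Grids must share a common alignment; the package validates but does not
  resample or reproject.
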