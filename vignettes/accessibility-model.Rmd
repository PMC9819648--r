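---
title: "Floating catchment accessibility with supply competition and multimodal travel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Floating catchment accessibility with supply competition and multimodal travel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkaccess)
```

## The model

Floating catchment area methods measure potential spatial access to
facilities as a supply-demand interaction in two passes. For parks, each
residential area `i` carries a population `D_i`, and each park `j` a capacity
`S_j` (its area) and a quality weight `W_j` (a visitor rating that proxies
how strongly the park competes for visits).

**Step 1 (facility view).** Every park's capacity is divided by the
decay-weighted population that can reach it within the travel-time threshold
`t0`:

$$R_j = \frac{S_j W_j}{\sum_{i:\, t_{ij} \le t_0} D_i\, G(t_{ij})}.$$

**Step 2 (resident view).** Every residence sums the ratios of the parks it
can reach, decay-weighted again:

$$A_i = \sum_{j:\, t_{ij} \le t_0} R_j\, G(t_{ij}).$$

`G` is either the all-or-nothing indicator (classic 2SFCA) or the normalized
Gaussian kernel

$$G(t) = \frac{e^{-\frac12 (t/t_0)^2} - e^{-\frac12}}{1 - e^{-\frac12}}
\quad (t \le t_0),$$

which equals 1 at zero cost, falls smoothly, and hits 0 exactly at the
threshold, so the Gaussian model is insensitive to whether the boundary is
inclusive. For the indicator kernel the boundary is inclusive
(`t_ij <= t0`).

Residents do not travel by a single mode, so the two steps run independently
per mode — each mode `M_n` with its own travel-time matrix, producing
`R_{j,M_n}` and `A_{i,M_n}` — and the final field is the convex combination
by the daily mode split:

$$A_i = \sum_n W_{M_n}\, A_{i,M_n}.$$

The default split (driving 25.7%, public transportation 43.2%, riding 8.6%,
walking 22.5%) is a published mode-share table for a large inland Chinese
city; any mix can be supplied and is renormalized to sum to one.

### Interpretation and key identities

`A_i` is in supply units per person (quality-scaled m² of park per resident
here). Two properties anchor the implementation and its tests:

* **Conservation.** When every park's catchment contains positive
  population, $\sum_i D_i A_i = \sum_j S_j W_j$: the model redistributes
  total weighted supply over the population, nothing more. The test suite
  checks this to a relative `1e-9` on random scenarios for both kernels,
  with and without quality weights.
* **Homogeneity.** Scaling all `W_j` by `c` scales every `A_i` by `c`;
  scaling all populations by `c` scales `A_i` by `1/c`. This is why the
  quality scores are used raw rather than normalized — a rescaling changes
  only the global unit. An optional min-max rescaling to `[0, 1]`
  (`rescale_scores()`, CLI flag `--rescale-scores`) is provided but off by
  default.

### Degenerate inputs and numerical choices

* A park whose catchment is empty (or contains only zero population) has an
  undefined ratio; it is set to `R_j = 0` with a warning, so isolated parks
  contribute nothing and the conservation identity simply omits them.
* A residence with no park in reach gets exactly `A_i = 0` — it cannot
  obtain park services within the threshold — never a small positive value.
* Unreachable origin-destination pairs are `+Inf`, never 0: a missing pair
  in an OD file silently treated as "zero minutes" would inflate
  accessibility, so absence means unreachable.
* All site tables are sorted by `site_id` at construction and every
  accumulation runs in that order, making floating-point results
  reproducible bit-for-bit across runs and input orderings.
* The Gaussian kernel clamps tiny negative round-off at the boundary to 0.
* Writers serialize doubles at 12 significant digits (CSV and GeoJSON
  alike), so written fixtures are stable golden files; read-write round
  trips agree to `1e-12`.

## Travel costs

The engine is agnostic about where travel times come from; the package
builds them two ways:

* `euclidean_matrix()` — straight-line planar distances, for the
  distance-threshold baseline. Comparing it with the time-based model shows
  the classic failure mode: a residence far from parks in meters but close
  in minutes (say, along a subway line) is misclassified by the baseline.
* `speed_time_matrix()` — a kinematic model per mode:
  `minutes = overhead + 60 * distance_km / cruise_speed`. Transit modes add
  corridor polylines; a trip takes the cheaper of walking directly or
  walking to a corridor, riding along it, and walking off (overhead applies
  to the corridor option only, as a boarding wait, so transit is never
  slower than walking). Projection onto corridors is by nearest point on the
  polyline; transfers between corridors are not modeled.

Default speeds are calibrated to reach envelopes rather than quoted as
ground truth: walking covers 2.7 km and riding 7 km in the 39-minute
threshold (4.15 and 10.77 km/h), and driving (40 km/h) covers the whole
default extent within it. These preserve the ordinal structure — driving
reaches everything, riding a wide disc, walking a narrow one, transit a
corridor-shaped region — which is what drives the spatial pattern of the
results. The 39-minute threshold itself is the published average daily
travel time in the study region; it is a parameter (`threshold_minutes`)
everywhere.

## The synthetic scenario

Real inputs of this kind (navigation-API travel times, census populations,
park ratings) are proprietary or bulky, so `generate_city()` draws a
seeded stand-in with the study's structure: 902 residential areas and 31
parks on a 13 × 10 km extent partitioned into 17 rectangular zones
(6 + 6 + 5 per row, south to north).

* Residential locations are uniform; populations log-normal (median 1000,
  `sdlog` 0.6) — right-skewed sizes typical of urban residential compounds.
* Park areas are log-normal (median 3 ha, `sdlog` 1), ratings uniform on
  3.5–5 (a 0–5 rating scale, where well-known parks rarely score below 3.5).
* The geography is deliberately unequal: a `park_area_skew` fraction
  (default 0.7) of the parks *and* of the total park area sits in the
  southern half, emulating a district whose dense northern core is
  park-poor while the southern suburbs hold the large parks. Drawn areas
  are rescaled so the south band holds the skew fraction of total area
  exactly. With `skew = 0.5` the layout is balanced and the north-south gap
  is centered near zero across seeds.

All draws flow from one seeded generator, so a scenario is reproducible
byte-for-byte. The generator emulates counts, scale, and the north-south
asymmetry; it does **not** emulate street networks, true sub-district
boundaries, spatially correlated population density, or realistic park
geometry. Passing tests therefore demonstrate that the machinery recovers a
built-in geography, not that it reproduces any real city's numbers.

## Zone aggregation and LISA

`aggregate_by_zone()` reports the population-weighted mean accessibility per
zone, `sum(D_i A_i) / sum(D_i)`; a zone with zero total population has no
defined mean and is returned as `NA`.

`local_moran()` classifies sites into HH/LL clusters and HL/LH outliers.
The underlying choices are standard LISA practice, made explicit because
the method's consumers only name the statistic:

* weights: k = 8 nearest neighbors (Euclidean, distance ties broken by site
  id), row-standardized; a distance-band scheme is also available;
* inference: 999 conditional permutations (the site's own value held fixed,
  the rest drawn without replacement into its neighbor slots), two-tailed
  pseudo p-value `(count(|I_perm| >= |I_obs|) + 1) / (n_perm + 1)` — the
  `+1` avoids zero p-values;
* labeling: significant at `alpha = 0.05` and sign of own deviation vs.
  spatial lag; everything else "not significant". A constant field is all
  "not significant" by construction (warning, no division by zero).

Permutations are drawn in sorted-site-id order from a required seed, so LISA
output is reproducible and invariant to row order. The local statistics obey
the identity `sum_i I_i = n * I_global` under row-standardized weights,
which the tests verify to `1e-9` against an independently cross-checked
global Moran's I.

## Problem sizes used in the checks

The packaged checks run the full pipeline at the study scale (902 × 31,
four modes, 999 permutations) for the qualitative-pattern and LISA checks,
and smaller randomized instances (up to 50 × 10) where an exhaustive
double-loop oracle is the comparison; these sizes make the whole suite run
in well under a minute while leaving every code path exercised at study
scale.

## Limitations

* Travel times are kinematic, not network-routed; congestion, timetables
  and transfers are out of scope.
* Catchment radii are fixed (one threshold for all sites and modes);
  variable-radius and three-step FCA variants are not implemented.
* The quality weight enters multiplicatively on capacity; other competition
  formulations (e.g. Huff-type choice probabilities) are not provided.
* LISA runs on the residential points; interpolated accessibility surfaces
  (kriging) are a presentation-layer concern and out of scope.
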