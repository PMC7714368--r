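---
title: "Methods: national responsibility and conservation priority from polygon overlays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: national responsibility and conservation priority from polygon overlays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nratool)
```

## The model

A national responsibility assessment asks how much of the conservation burden
for a species falls on a given administrative unit. The quantities are purely
geometric. With distribution area $D$, reference area $R$ and focal area
$F \subseteq R$:

$$DP_{exp} = \frac{\lvert D \cap R \rvert}{\lvert R \rvert}, \qquad
  DP_{obs} = \frac{\lvert D \cap F \rvert}{\lvert F \rvert}.$$

$DP_{exp}$ is the share of the reference area the species occupies: if the
species were spread indifferently, any focal area would hold about this
proportion of its own territory under the species' range. $DP_{obs}$ is the
share actually held. $DP_{obs} > DP_{exp}$ marks the focal area as
over-represented — it contains disproportionately much of the range, hence a
larger share of the responsibility.

The second ingredient is the **distribution pattern** of the within-reference
range over biogeographical units (environmental zones, ecoregions or any
polygon partition of the reference area):

* *PC-A* (count approach): `n_units` occupied units, with defaults
  $n \le 1$ local, $2 \le n \le 3$ regional, $n \ge 4$ wide. The literature
  treats these borders as adjustable; they are `nra_config()` fields
  (`pc_local_max`, `pc_regional_max`) and every output summary prints them,
  so no run can silently depend on hidden thresholds.
* *PA-A* (area approach): per-unit area shares of the within-reference
  range. One occupied unit is local; otherwise the range is regional when the
  largest share $p_{max}$ reaches `pa_regional_fraction` (default $2/3$), and
  wide otherwise. The boundary is inclusive — $p_{max} = 2/3$ exactly is
  regional — because the defining phrase is "two-thirds of the distribution
  area located in one region". The PA-A is the more finely resolved of the
  two but is sensitive to area distortion, so it should only be used with an
  equal-area or geodesic area computation.

Pattern is a per-species property computed once against the reference area,
not per focal feature; only the $DP$ comparison varies across countries.

The decision tree maps (pattern, over-represented?) to the responsibility
class:

| pattern  | not over-represented | over-represented |
|----------|----------------------|------------------|
| local    | high                 | very high        |
| regional | medium               | high             |
| wide     | basic                | medium           |

This is the unique mapping onto the four classes that is monotone in both
arguments (narrower pattern never lowers the class; over-representation never
lowers it) and is consistent with the canonical narratives: a country hosting
essentially all of a single-region endemic scores very high, a country
clipping the edge of a continent-wide generalist scores basic. The table is
data, not code — `nra_config(nr_mapping = ...)` accepts a replacement, which
is validated for monotonicity and printed in every summary. A species absent
from a focal area (overlap at or below sliver tolerance) gets class *none*
there.

Finally, responsibility is crossed with the species' global IUCN Red List
category in the fixed 24-entry class/score table (`build_priority_matrix()`).
The scores are irregular by construction and are shipped as literal data;
they are deliberately never derived from a formula. Data Deficient and Not
Evaluated categories have no row, so such species (and species with
responsibility *none*) are flagged not evaluable rather than scored.

## Geometry engine and numerical choices

No vector-GIS binding is assumed: the package carries its own overlay engine
for polygon *area* computations. Geometries are multipolygons whose rings are
straight-line paths in coordinate space. Boolean intersection areas are
computed by ear-clipping each ring into triangles and clipping convex pieces
pairwise (Sutherland–Hodgman); holes contribute negatively signed pieces, so
areas are exact for valid nested-ring inputs. This choice trades generality
(no union geometry output, no buffering) for a small, fully testable core;
the dissolve operation therefore represents a union as a grouped multi-part
feature, which is a valid union precisely when the inputs do not overlap —
the expected situation for a biogeographical partition. Overlaps above the
sliver tolerance trigger a warning and are counted toward every overlapping
unit, as overlapping "partitions" signal defective input rather than a case
to silently resolve.

Numerical conventions:

* **Area modes.** `auto` chooses geodesic (WGS84 ellipsoidal, via
  `geosphere`) for geographic CRS and planar shoelace area for projected CRS;
  the mode never reprojects coordinates. Geodesic edges follow the
  lon/lat-linear path of the ring (edges are densified to 0.05° steps before
  the ellipsoidal integral), matching the clipping engine's geometry, so
  areas remain additive under subdivision to about $10^{-6}$ relative.
* **Sliver tolerance** (default $10^{-9}$ of the reference area) decides both
  species presence in a focal area and whether a unit counts as occupied.
  Boundary-touching contact along a line has zero area and never counts.
* **Proportions** are clamped to $[0,1]$ after overlay to absorb
  floating-point slivers.
* **Ties.** The default comparison is strict ($DP_{obs} > DP_{exp}$): a tie
  carries no evidence of over-representation and resolves to the lower class.
  `strict_comparison = FALSE` switches to $\ge$.
* **Geometry repair** on ingestion is limited to closing, deduplicating and
  re-orienting rings (logged); rings with genuine self-intersections are
  rejected naming the feature, because a silent guess at the intended region
  would bias every downstream area.
* **Quartiles** in `compare_approaches()` are inclusive linear interpolation
  (`stats::quantile` type 7), and countries are ranked by descending PC-A
  count with ties sharing the smallest rank; the rounded quartile thresholds
  and the ranking convention are part of the output rather than an implicit
  choice.

## The synthetic toy world

`make_toy_world()` generates the test universe: a $100 n_c \times 100$ km
planar reference rectangle tiled exactly by $n_c$ country strips and $n_u$
horizontal unit bands, with four archetype species modelled on the classic
shrew illustration:

* *endemic* — one country, one unit (expected: local, very high in the host
  country, none elsewhere); category EN;
* *regional_closed* — spans two countries with $\approx 71\%$ of its area in
  one unit (regional under both approaches); category VU;
* *disjunct* — two separated patches in different units and countries; two
  occupied units make it regional under PC-A but $p_{max} = 0.5$ makes it
  wide under PA-A, so the two approaches genuinely diverge; category NT;
* *widespread* — covers most of every unit and country (wide under both);
  category LC.

All truths (areas, proportions, occupancy, patterns, classes) are computed by
closed-form rectangle arithmetic inside the generator, independently of the
overlay engine, so an end-to-end run can be checked against analytic values.
The default sizes ($n_c = 4$, $n_u = 5$) keep every test in milliseconds.
The world is deliberately idealized: axis-aligned ranges, exact tilings, no
holes, no datum issues, no range-map digitization noise. Passing tests
therefore demonstrate correctness of the computation, not robustness to the
messiness of real range polygons — for real data the containment checks,
repair log and warnings in the summary are the guard rails. Geographic-CRS
behaviour is exercised separately against the spherical closed form
$R^2 \, \Delta\lambda \, (\sin\varphi_2 - \sin\varphi_1)$ (authalic radius)
and an equal-area weighted raster oracle; a degree cell at the equator agrees
with the authalic closed form to about 0.45%, the intrinsic
ellipsoid-vs-sphere difference.

The independent raster oracle (`raster_oracle_area()`, grid-centre counting
with `mgcv::in.out`) deliberately shares no code with the clipping engine;
its error is bounded by the perimeter times the cell size.

## Scope and limitations

* Inputs are GeoJSON polygon layers (plus CSV metadata and semicolon species
  lists); outputs are GeoJSON maps, dBase III + CSV attribute tables (field
  names truncated deterministically to 10 characters, with the truncation map
  in the summary) and an ASCII run summary.
* The reference area must enclose every focal feature; species ranges
  extending beyond it are clipped with a warning (or rejected under the
  `error` policy), and the containment ratio is reported per species.
* Abundance weighting, national red-list inputs, raster inputs and
  reprojection are out of scope; the global IUCN category is the only threat
  input.
* Responsibility scores are comparable only within one assessment (same
  reference area, units and configuration).
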