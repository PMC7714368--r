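# nratool

National responsibility and conservation priority assessment for species
distributions in R.

Conservation resources are finite, and the responsibility for conserving a
species is shared unevenly among the countries its range touches: a country
holding most of the world range of a narrowly distributed species matters far
more to that species' persistence than a country clipping its edge. `nratool`
determines, for every (species, country) pair, a **national responsibility
(NR)** class and a **conservation priority (CP)** class and score from polygon
overlays of four vector layers: species distribution ranges, biogeographical
units (e.g. environmental zones or ecoregions), focal areas (the countries or
administrative units under assessment), and a reference area that encloses
them. It is aimed at conservation biogeographers and policy analysts preparing
regional or national prioritization reports.

## Method

For a species with distribution area *D*, reference area *R* and focal area
*F*, two proportions are compared:

- expected distribution proportion:  DP_exp = area(D ∩ R) / area(R)
- observed distribution proportion:  DP_obs = area(D ∩ F) / area(F)

DP_obs > DP_exp means the focal area holds a higher share of the species'
range than its size alone would predict. The species' within-reference range
is also classified into a **distribution pattern** — *local*, *regional* or
*wide* — by one of two approaches:

- **PC-A** (Polygon Count-Approach): from the number of biogeographical units
  the range occupies (defaults: 1 unit local, 2–3 regional, 4+ wide;
  configurable and printed in every summary);
- **PA-A** (Polygon Area-Approach): from per-unit area shares of the range
  (single unit local; largest share ≥ 2/3 regional, inclusive; otherwise
  wide).

A decision tree combines pattern and comparison into the NR class (basic,
medium, high, very high; *none* if the species is absent from the focal
area), and the NR class is crossed with the species' global IUCN Red List
category in a fixed 6 × 4 class/score table to yield the CP class (1–4) and
score (2–25). Data Deficient and Not Evaluated species are assessed for
responsibility but are not evaluable for priority.

Areas are geodesic (WGS84 ellipsoid) for geographic coordinates and planar
for projected coordinates; vector overlay is exact polygon clipping, not
rasterization.

## Worked example

The package ships a deterministic synthetic toy world — four country strips,
five environmental-zone bands and four archetype species (an endemic, a
regionally concentrated range, a disjunct two-patch range and a widespread
generalist) with analytically known areas:

```r
library(nratool)
world <- make_toy_world(seed = 1)
meta  <- data.frame(species_id = names(world$iucn),
                    iucn_category = unname(world$iucn))
run <- assess(toy_layerset(world), meta, nra_config(approach = "count"))
run$records[, c("species_id", "focal_id", "dp_exp", "dp_obs",
                "pattern", "nr", "cp_class", "score")]
```

```
        species_id focal_id dp_exp dp_obs  pattern        nr cp_class score
1          endemic       C1  0.012  0.048    local very_high        1    20
2          endemic       C2  0.012  0.000    local      none       NA    NA
...
5  regional_closed       C1  0.070  0.112 regional      high        2    13
...
13      widespread       C1  0.855  0.810     wide     basic        4     2
14      widespread       C2  0.855  0.900     wide    medium        4     3
```

Reading the first row: the endemic species occupies 1.2% of the reference
area but 4.8% of country C1, so C1 is over-represented; a local,
over-represented species gives *very high* responsibility, and crossing that
with its Endangered status gives conservation priority class 1, score 20.
Every other country has no overlap with the endemic and carries no
responsibility for it. The widespread species yields only basic/medium
responsibility everywhere, as its observed shares hover around its 85.5%
expected share.

`write_outputs()` emits per-species GeoJSON maps, a dBase + CSV attribute
table and an ASCII summary; `compare_approaches()` contrasts PC-A and PA-A
species-per-country counts with quartile statistics and rank agreement.

The same workflow is available from the shell:

```sh
Rscript inst/cli/nra-tool.R fixtures --seed 1 --out fixtures/
Rscript inst/cli/nra-tool.R assess \
  --species-dir fixtures --units fixtures/g-units.geojson \
  --reference fixtures/g-reference.geojson --focal fixtures/f-countries.geojson \
  --metadata fixtures/metadata.csv --approach count --out results/
```

Input files follow the naming convention `s-<species>` (ranges), `g-*`
(units / reference) and `f-*` (focal areas); unconventionally named files are
rejected unless a role is forced.

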