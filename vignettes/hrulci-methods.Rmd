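---
title: "Methods: the HRU-based location-weighted landscape contrast index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the HRU-based location-weighted landscape contrast index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrulci)
library(dplyr)
```

## The model

Non-point source pollutants travel from the plots that generate them,
across intervening landscapes, to the stream network.  Whether a plot acts
as a net *source* (cultivated land, residential land, orchards) or *sink*
(forestland, water, unused land) depends both on what it is and on where
it sits.  The index this package computes makes that location-dependence
explicit at the scale of the **hydrological response unit (HRU)** — the
smallest unit that is internally homogeneous in land use and soil and lies
within one sub-basin, so a single weight per unit is physically
meaningful.

Per HRU $i$ and pollutant (TN, TP or COD):

$$\mathrm{HRULCI}_i = W_i \times A_i$$

with $A_i$ the area in hectares and $W_i$ the generation/inhibition
weight.  $W_i$ is a function of eight geographic correction factors; this
package composes them as a product,

$$W = L \cdot P \cdot R \cdot D \cdot N \cdot S \cdot F \cdot A,$$

the standard export-coefficient correction scheme.  The product form was a
genuine design choice (only the functional dependence, not the
composition, is dictated by the index definition): it makes the
standard-farmland baseline exactly 1, makes any annihilating factor
(distance beyond the cap) zero out the weight, and makes factor effects
independent multipliers.  A weighted arithmetic mean is available via
`hru_weights(..., composition = "mean")` for sensitivity analysis.

Weights are standardized per pollutant across all HRUs of the basin,
$W_i / W_{\max}$, before the area multiplication, so the most
pollution-prone unit scores exactly 1 and indices are comparable across
pollutants.  We read "the maximum over a certain landscape" as the global
basin maximum; per-land-use-class normalization is a plausible alternative
reading and can be obtained by grouping before `normalize_weights()`.
Pollutant indices add per HRU, and sub-basin scores are plain member sums
— both identities are exact and tested to 1e-9 relative tolerance.

### The per-unit-area column

$W_i \times A_i$ is extensive: comparing it against the scalar threshold
1 mixes units.  The statement "cultivated land scores above 1, forest
below 1" only becomes well defined per unit area, so `hrulci()` reports a
separate `per_area_index` column equal to the *raw* (un-normalized)
weight, i.e. the unit's export propensity relative to the
standard-farmland baseline of 1.  All threshold-1 statements in the
package refer to this column.

## The correction coefficient table

Each factor partitions its domain into classes with one multiplier per
class; interval classes are lower-closed, upper-open.  The baseline class
of every factor — the one standard farmland occupies — has coefficient
exactly 1 by validated invariant.  Defaults:

| Factor | Classes (baseline in bold) | Coefficients |
|---|---|---|
| L land use | cultivated (**baseline**), orchard, other, forest | 1.0, 0.85, 0.6, 0.3 |
| P slope | **[0, 25°)**, [25°, ∞) | 1.0, 1.2 |
| R precipitation | [0, 400), **[400, 800)**, [800, ∞) mm | 0.8, 1.0, 1.3 |
| D distance | linear decay, 1 at 0 m, 0 at ≥ 20 km | continuous |
| N NDVI | 1 at NDVI ≤ 0, linear to 0.3 at NDVI = 1 | continuous |
| S texture | sandy, **loam**, clay | 1.1, 1.0, 0.9 |
| F fertilizer | [0, 375), **[375, 525)**, [525, ∞) kg/ha/yr | 0.8, 1.0, 1.2 |
| A moisture | low, **medium**, high | 0.9, 1.0, 1.1 |

Only the *ordinal structure* of this table is load-bearing for the
package's conclusions (steeper, wetter, more fertilized export more;
vegetated and distant units export less; cultivated > orchard > other >
forest): every test and acceptance property depends on the ordering and
the baseline-equals-1 convention, never on the particular magnitudes,
which stand in for a regional calibration and are fully overridable via a
validated YAML file (`read_coefficients()`).  Three notes on contested
points:

* **Land-use classes.**  The factor scheme is sometimes stated with
  cultivated land and orchards sharing one class.  We keep them separate:
  orchard soils are more compact and tree cover conserves soil and water
  better than annual crops, so a single shared multiplier would erase a
  distinction the analysis itself reports.
* **Fertilizer units.**  Class bounds of "25 kg" and "35 kg" only
  reconcile with the standard-farmland band of 375–525 kg/ha/yr if read
  as kg per mu (1 mu = 1/15 ha); the table therefore stores 375 and 525
  kg/ha.
* **Distance.**  The 20 km cap is the stated maximum influence distance;
  the decay *shape* between 0 and 20 km is not specified anywhere, and we
  use the simplest monotone choice (linear).  Distances are
  center-to-center Euclidean to the nearest water cell (exact two-pass
  parabola-envelope transform); flow-path distance would be a natural
  extension but requires committing to a routing model for the distance
  factor too.

Continuous factors are aggregated to HRUs by the area-weighted mean over
member cells *before* classification; categorical factors come from the
HRU's defining codes (soil moisture, which is not part of the HRU
definition, uses the modal class).

## HRU delineation

Depression filling uses priority-flood with a 1e-6 m epsilon gradient on
filled flats, which guarantees every cell a strictly descending D8 path
and hence an acyclic flow field (verified by topological sort in every
test run).  D8 steepest descent breaks ties deterministically in the order
E, SE, S, SW, W, NW, N, NE.  Streams are cells whose flow accumulation
meets a threshold (default 100 cells ≈ 9 ha at 30 m resolution — a desk-
scale stand-in for the usual calibration against a mapped network);
the network splits into segments at junctions, every cell is labelled by
the first segment its flow path reaches, and HRUs are the connected
components of the sub-basin × land-use × soil overlay.

Two open choices resolved here: HRUs are *contiguous* components rather
than scattered same-code unions (SWAT-style), because a per-HRU distance
factor is only meaningful for a spatially coherent unit; and undersized
HRUs (default below 5 cells) are absorbed by the same-sub-basin neighbour
sharing the longest boundary (ties: larger area, then lower id), adopting
the absorber's codes so the single-code invariant survives merging.  An
undersized HRU with no same-sub-basin neighbour is kept with a warning
rather than merged across a drainage divide.

## Landscape metrics

The eight metrics follow the classical raster formulations: patch
connectivity defaults to 8 (queen) while like- and inter-class adjacency
for AI/IJI use single-counted rook edges; LSI normalizes total inter-class
edge by the circumference of the equal-area circle, $E / 2\sqrt{\pi A}$;
patch shape is $0.25\,p/\sqrt{a}$ (square = 1), area-weighted for AWMSI;
ENN is the center-to-center distance between cell sets of same-class
patches, defined only for classes with at least two patches; AI is
$100\,g_{ii}/\max g_{ii}$ with the largest-square packing bound, treating
single-cell classes as fully aggregated; IJI is the entropy of the
inter-class edge distribution relative to its maximum, defined for three
or more classes.  The grid border is neutral: it counts toward patch
perimeter but never toward inter-class edge.  Every metric is checked
against an independent brute-force implementation (label propagation,
per-edge enumeration, all-pairs distances) on randomized rasters.

Patch density is reported per 100 ha.  Published PD values for this
method's study area are not dimensionally consistent with the
accompanying patch counts and basin area under any standard unit, so PD
is validated against its definition only, not against printed tables.

## The synthetic basin

The generators stand in for the satellite, DEM and soil layers a real
application would use, and their defaults *are* the study conditions of
the package's tests: a 64 × 64 grid of 30 m cells (about 3.7 km²),
120 m of relief on a south-draining tilted plane with smooth bumps,
forest-dominated cover (55 %) with cultivated land (30 %) and orchards
(15 %), patch clustering 0.7, annual precipitation 1200–1600 mm, and
fertilizer at 600 kg/ha/yr on cultivated land and 450 on orchards.  The
precipitation and fertilizer levels describe a subtropical coastal
catchment under intensive agriculture — precipitation well above the
800 mm class bound and cultivated-land fertilization above the standard
band — which is exactly the regime in which cultivated land exports more
than standard farmland.  NDVI is drawn per class (forest 0.80, orchard
0.55, cultivated 0.35, sd 0.08) and the red/NIR bands are constructed to
invert exactly to it; soil texture and moisture are independent
smoothed-noise mosaics (25/50/25 %).

Everything is deterministic per (scenario, seed) with seed threading that
never touches the caller's RNG state.  The smoothing width that maps
`patch_clustering` to patch size (sigma = 10 · clustering cells) is a
fixed calibration constant: at clustering 1 a two-class 64 × 64 map
realises at most a handful of patches, at 0 the cells are i.i.d.

What the generators do *not* emulate: real class geometries (field
boundaries, road networks, riparian buffers), spatial correlation between
soil and terrain, seasonal NDVI, and measured export coefficients.
Passing tests therefore demonstrate that the machinery is correct and
that the index reproduces the expected source–sink ordering under
realistic-magnitude inputs — not that the default coefficients are
calibrated for any particular basin.

## Numerical choices and limitations

* Problem sizes: tests run on rasters up to 64 × 64 and oracle
  comparisons up to 16 × 16 over dozens of seeds; all algorithms are
  O(n log n) or better per layer and scale to realistic grids.
* Nodata: `NA` cells propagate through all arithmetic; -9999 on write.
  Category code 0 is reserved.
* The distance transform is exact (squared-distance lower envelope), not
  a chamfer approximation.
* Horn slope uses edge replication at the border, which flattens border
  gradients; border HRUs in steep terrain inherit slightly low slopes.
* Kappa is undefined when chance agreement is exactly 1; flagged `NA`.
* The index is relative: it ranks units and sub-basins and tracks change
  over time, but converting it to absolute loads requires the baseline
  export coefficients (kg/ha/yr) and local calibration.
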