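---
title: "Methods: from geodata layers to personal exposure variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from geodata layers to personal exposure variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposcape)
```

## The problem

Epidemiological cohorts record where people live; environmental geodata
record what surrounds those places. To relate the two, each environmental
attribute has to be *operationalised as a personal exposure*: a single
number per residential address (or per postal-code area or administrative
neighbourhood) summarising the attribute over that person's spatial
context. exposcape implements the standard processing chain for this —
exposure zones, kernel density surfaces, zonal statistics, composite
indices, and table export keyed by address or administrative unit — plus a
deterministic synthetic-city generator so every step can be exercised and
verified without access to national geodata.

All computation assumes a single projected metric CRS (coordinates in
metres). The package refuses input that declares a geographic (lon/lat)
CRS rather than reprojecting silently: buffers, kernel radii and areas are
only meaningful in planar metres, and a silent reprojection would hide a
substantive modelling choice from the user.

## Exposure zones

A personal exposure is a statistic over an *exposure zone*. Two zone
families are supported:

* **Circular buffers** of radius 100–2000 m around each address
  (`make_buffers()`; presets `EXPOSURE_RADII` = 150, 250, 350, 500, 750,
  1000, 1650, 2000 m). Circles are approximated by regular polygons with
  vertices on the true circle. We use 128 segments: the inscribed-polygon
  area deficit is `1 - (n/2π)·sin(2π/n)` ≈ 0.04% at n = 128, comfortably
  inside the 0.1% area tolerance we test; at n = 64 the deficit (0.16%)
  would exceed it.
* **Administrative units** (`admin_units()`, `admin_zones()`):
  neighbourhood, PC4, PC6, district, municipality.

Zone statistics use two deliberate conventions, stated here because the
tools this emulates leave them implicit:

* **Cell-centre rule** for rasters: a cell contributes to a zone iff its
  centre lies in the zone. No area-weighting of partial cells. This
  matches the moving-window behaviour of the common GIS implementations
  and makes the brute-force oracle in the test suite exact.
* **Closed zones** for points: a point exactly on the zone boundary
  counts as inside. Some convention is required; the closed one is easiest
  to reason about and is asserted in tests.

Land-use area shares (`zonal_polygon_share()`) are computed by exact
Sutherland–Hodgman clipping, which requires **convex** zones — true for
buffers and rectangular admin tiles; non-convex zones raise an error
rather than returning an approximation. Overlapping same-class polygons
are dissolved via inclusion–exclusion over connected overlap groups
(exact for convex members) so area is never double-counted.

## Quartic kernel density

Distance-weighted access measures use the quartic (biweight) kernel: a
point at $x_i$ with weight $w_i$ contributes to a cell with centre $c$

$$
K(d) = w_i\,\frac{3}{\pi r^2}\Bigl(1 - \tfrac{d^2}{r^2}\Bigr)^2,
\qquad d = \lVert c - x_i \rVert < r,
$$

and exactly zero at and beyond the search radius $r$. The surface value
is the sum over all points within $r$ of the cell centre — evaluation at
cell centres only, no within-cell integration, again matching the
standard GIS behaviour. Densities are per m²; `output_units = "per_km2"`
scales by exactly 10⁶.

Properties that follow and are asserted in the test suite: compact
support (exact zeros), peak value $3/(\pi r^2)$ at the point, cell-wise
superposition, monotone decay along rays, and mass conservation — for a
point at least $r$ from every raster edge, the cell sum times cell area
recovers the point weight within 1% at `cell_size = r/20`, refining as
the cell shrinks. **No edge correction** is applied: mass of points near
the raster boundary is partly lost, as in the source tools; the mass test
is therefore restricted to interior points.

`cell_size` defaults to `r/10`, a compromise between the ~1% mass error
of coarse grids and quadratic runtime growth; it is configurable
everywhere.

## Inverse-distance-weighted interpolation

Station observations (e.g. temperature) are interpolated with IDW:
prediction $= \sum_i d_i^{-p} z_i / \sum_i d_i^{-p}$ over stations with
$0 < d_i \le$ `search_radius`. Defaults follow national-scale practice
for station networks: power $p = 2.0$, search radius 110 km, optional
20 km block size. A cell centre coinciding with a station returns the
station value exactly (the conventional short-circuit), and cells with no
station in range become missing rather than extrapolated.

"Block size" is not given precise semantics by the tools that advertise
it; we implement **block-mean prediction**: cell-centre predictions are
averaged within non-overlapping `block_size` squares aligned to the
raster origin, and the mean is assigned to every member cell. The
alternative reading (a neighbour-search optimisation) would not change
values where station density is high; users who want unblocked surfaces
simply omit `block_size`.

## Land-use mix entropy

The mix construct is normalised Shannon entropy over the $k = 5$ tracked
land-use classes (residential, commercial, social-cultural services,
offices/public services, greenspace/recreation):

$$
E = -\frac{\sum_{i:\,p_i>0} p_i \ln p_i}{\ln k},
$$

with $p_i$ the class area shares renormalised over the tracked classes.
The construct is named "entropy index" in the walkability literature
without a formula; normalised Shannon entropy is the standard choice
there and is recorded in the emitted metadata sheets. $E = 0$ for a
single-use zone, $E = 1$ for five equal shares, $\ln 2/\ln 5 \approx
0.4307$ for a 50/50 two-class split. A zone containing none of the
tracked classes gets `NA` (there is no mix to measure), not 0.

## Street connectivity

Connectivity is the ratio of *true intersections* — network nodes where
**three or more** distinct legs meet — to zone area in km². The network
is first planarized (`planarize_network()`): polylines are split into
elementary segments, segments are split at mutual crossing points, and
endpoints are merged within a 0.01 m snap tolerance. A crossing of two
through-streets therefore counts 4 legs even when the input geometries
share no vertex; a T-junction counts 3 and is an intersection; a bend or
pass-through vertex counts 2 and is not.

## The walkability index

The composite index sums the z-scores of six components — population
density, retail/service destination density, land-use mix, street
connectivity, green-space density, sidewalk density — and rescales the
sums to 0–100:

$$
\mathrm{score}_i = 100\cdot
\frac{S_i - \min_j S_j}{\max_j S_j - \min_j S_j},
\qquad S_i = \sum_{c=1}^{6} z_{ic}.
$$

Choices made where the construct's description is open, all recorded in
the metadata sheets:

* **Equal weights** for the six components ("summing" implies weights 1).
* **Sample (n−1) SD** for z-scores.
* **Min–max rescaling** to 0–100 ("normalizing" is otherwise
  unspecified); the least/most walkable zones in the reference set score
  exactly 0 and 100.
* **The reference set is the set of zones in the run.** Scores are
  therefore *run-relative*: a score of 80 means "near the top of this
  study region", not an absolute standard. Comparing scores across runs
  requires scoring all zones in one run.
* The land-use-mix component z-scores the entropy value itself.
* In the bundled pipeline, population density uses the address layer as
  the population carrier (weights = persons per point when available) and
  sidewalk density uses centreline length per km² of zone — the synthetic
  city has no separate sidewalk polygon layer, and length density is the
  natural line-layer analogue of the polygon-area density used with real
  sidewalk data.

Degenerate inputs are rejected loudly: a component that is constant over
the reference set has no z-score (error naming the component), as does a
run where all component sums coincide. A zone missing one component gets
an `NA` score; the remaining zones are still scored.

## MAUP-mitigated aggregation

When exposures must be delivered on administrative units, naive
count-per-area aggregation makes the result depend on unit shape and
scale (the modifiable areal unit problem) and discards everything just
across the border. `kernel_then_aggregate()` implements the mitigation:
build the kernel density surface first, then average it over each unit.
A point 50 m inside unit A with a 1000 m kernel then contributes to
neighbouring unit B's value (strictly positive, while the naive value is
exactly 0) — cross-border environment information enters the aggregate.
The contrast function `naive_aggregate()` and the helper
`maup_sensitivity()` (same computation across several tilings and radii,
reporting dispersion) let users quantify how much the mitigation matters
at their scale. The default kernel radius is 1000 m — the one radius the
source practice documents for this purpose — and is configurable.

Two properties pin the procedure down in tests: across-unit variance of
the kernel-based estimates never exceeds the naive variance (for kernel
radius ≥ unit side, over several seeds), and total mass is conserved:
the area-weighted sum of unit means recovers the point count within 5%
(discretization plus edge loss) for interior points.

## The pipeline and its provenance record

`run_pipeline()` drives everything from one manifest (a YAML file or the
equivalent list): a seed, a synthetic-city configuration, a list of
variable recipes (`point_density`, `kernel_density`, `entropy`,
`land_use_share`, `connectivity`, `idw`, `walkability`), and a linkage
level. Output columns are named `<theme>_<stat>_A<radius>_<year>`, every
column gets a metadata sheet (source layer, zone, processing steps,
formula choices, units), and the run log records feature counts per
stage so spot checks can be scripted. Unknown recipes fail *before* any
computation; a variable whose computation fails is skipped with the
reason logged, without aborting the run.

Aggregation from address level to PC4/neighbourhood (`link_level()`)
uses the per-unit **mean** of address values with an `n_addresses`
contributor count — the delivery statistic is otherwise unspecified in
practice, and the mean plus count lets users reconstruct sums or weight
by coverage.

Determinism is a contract, not an aspiration: generators draw from
per-generator seeded streams (so adding a layer never perturbs another),
and `write_exposure_table()` formats numbers with 17 significant digits,
so identical manifest + seed gives byte-identical CSV output. This is
asserted in the test suite.

## What the synthetic city does and does not emulate

`city_config()` defines a rectangular region (default 5 × 5 km) with an
orthogonal street grid (250 m spacing — a dense urban grid), square
land-use patches (250 m side) drawn from the five classes with shares
approximating a Dutch urban mix (residential 0.40, commercial 0.15,
social-cultural 0.10, offices/public 0.15, greenspace 0.20), uniformly
placed points of interest, addresses and stations, and exact k × k
admin tilings at two nesting levels. Stations carry values from a known
smooth surface so interpolation recovery is checkable by construction.

This is sufficient to verify every computational contract above, but it
is *not* a model of real geography: no clustered settlement structure,
no curved or hierarchical road topology, no spatial autocorrelation in
land use, no irregular administrative borders, no measurement error in
station values. Passing tests demonstrate that the operators compute
their definitions exactly and behave correctly under composition — not
that any particular real-world exposure gradient will be recovered.

## Numerical choices and limitations

* Polygon containment is boundary-inclusive ray casting; the independent
  test oracle uses winding numbers.
* Polygon repair is limited to duplicate/collinear vertex removal and
  ring closure; self-intersecting polygons that survive this are
  rejected with a validation error, never silently "fixed".
* Raster I/O uses the Esri ASCII grid (text) format with 17-significant-
  digit output, making write-then-read round trips value-exact. GeoTIFF
  input is detected and rejected with a clear message.
* Node snapping in planarization uses a 0.01 m tolerance grid; networks
  with genuine geometry at sub-centimetre scale would need a smaller
  tolerance.
* Problem sizes in tests (40 × 40 grids, 25–100 addresses, ≤ 200
  points) are chosen so the full suite, including brute-force oracles,
  runs in well under two minutes; all operators scale to larger inputs
  with the documented complexity (kernel: O(points · cells within r);
  planarization: O(segments²)).
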