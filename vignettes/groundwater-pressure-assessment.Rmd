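---
title: "Grid-based assessment of anthropic pressures on groundwater"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based assessment of anthropic pressures on groundwater}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwpressure)
```

## The problem and the model

Karst aquifers — thin soils, caves, sinkholes — are exceptionally exposed to
surface contamination, and routine monitoring budgets rarely stretch to
sampling every well. `gwpressure` implements a quali-quantitative screening
method for deciding *where* a fixed budget of monitoring wells buys the most
information: give more wells to the parts of the territory that carry more
potential contamination sources.

The method is a weighted overlay on a regular tessellation:

1. **Grid.** The study area is divided into square blocks of side $d$
   (default 10 km). Coastal clipping leaves fragments; fragments at or below
   half a cell are merged into a neighbour, so every analysis unit is of
   comparable size.
2. **Layers.** Each type of pressure (waste-water discharges, IPPC plants,
   contaminated sites, waste-management companies, atmospheric emitters, PCB
   plants, livestock farms, active quarries, landfills,
   major-accident-hazard industries, disused quarries, sinkholes) is a
   georeferenced point set with an attributed weight $w_i \in [0,1]$
   reflecting its potential impact on groundwater. The weights are
   expert-judgment inputs, not fitted quantities; eleven layers are
   anthropic, sinkholes are the one natural pressure.
3. **Score.** Block $b$ receives
   $$S_b \;=\; \sum_{i=1}^{12} n_{b,i}\, w_i ,$$
   where $n_{b,i}$ is the number of points of layer $i$ falling in the
   block. Containment only: a source influences the block it sits in, with
   no distance decay onto neighbours.
4. **Classes and wells.** Reported scores (1 decimal place) are binned into
   four classes with upper edges 10, 20 and 30, and blocks receive 1, 2, 3
   or 4 monitoring wells according to their class.

Everything downstream of the weights is pure arithmetic, which is what makes
the method auditable: the per-layer totals $n_i w_i$, the block scores and
the well counts can all be recomputed by hand from the tables the pipeline
prints.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cell_size` | 10 000 | m | side of a grid block |
| `min_area_fraction` | 0.5 | — | blocks at or below this fraction of $d^2$ are merged |
| `upper_edges` | 10, 20, 30 | score | class boundaries (half-open, on the 1-decimal score) |
| `wells_per_class` | 1, 2, 3, 4 | wells/block | monitoring intensity per class |
| layer weights | see `default_registry()` | — | impact of one source of each type |

The defaults reproduce the published study setup end to end; changing any of
them is supported but changes the meaning of the output classes.

## Design choices where the method description is open

Several operational details are not fixed by the method's published
description; the package resolves them as follows, once, and treats them as
part of its contract.

* **Grid anchor.** The grid is anchored at the lower-left corner of the study
  area's bounding box (an `origin_offset` is accepted). Any anchor is as
  defensible as any other; this one is reproducible from the data alone.
  Because the anchor is a modelling choice, the exact published 32-block
  layout of the original province is not reconstructible — its anchor was
  never stated — and the package does not try.
* **Half-open cells.** Cells are half-open intervals in both axes, so every
  point of the plane belongs to exactly one cell and no point is ever
  double-counted. A point exactly on an interior grid line belongs to the
  cell above/right of it. For the rare points whose cell lookup fails after
  clipping (e.g. exactly on the area's bounding-box edge), membership is
  tested against final block geometries in ascending `block_id` order and
  the first containing block wins — again: counted exactly once.
* **Merge target.** "Merge into the nearest neighbour" is implemented as the
  neighbour sharing the *longest in-area boundary*, ties broken by smallest
  `block_id`. This is a deterministic, geometry-driven proxy for nearness
  that cannot orphan a fragment whose centroid happens to sit oddly. The
  threshold is inclusive — a block at exactly half a cell merges — because
  the half-cell fragment is the canonical case the rule exists for. An
  undersized block with no neighbour at all (an islet) is kept and flagged
  with `".unmergeable"` in `merged_from` rather than silently dropped.
* **Class edges.** The published class bounds appear in two renderings
  (1-decimal and 2-decimal, with gaps between classes). Both collapse to the
  same gap-free rule once scores are rounded to the reporting precision:
  half-open intervals $(\,\cdot\,,\text{edge}]$ on the 1-decimal score, so
  10.0 is first class and 10.05 (which reports as 10.1) is second. The top
  class is unbounded — the published 42.5 ceiling is an observed maximum,
  not a bound.
* **Zero-score blocks.** The nominal first-class interval starts at 0.1, but
  every block of the original study received at least one well. Scores below
  0.1 — including an exact 0 — therefore fall in class 1: every block is
  monitored.
* **Well coordinates.** How many wells a block gets is the method's output;
  *where* in the block to drill is not. `place_wells()` offers optional
  conveniences (`centroid` with a deterministic golden-angle jitter for
  multi-well blocks, `pressure_weighted` snapping to the highest-weight
  sources) and defaults to `none`.

## Numerical choices

* **Geometry** goes through the Clipper polygon engine (`polyclip`), with an
  explicit snapping resolution of $10^{-8}$ m. Clipper's default resolution
  (about $10^{-9}$ of the coordinate range, i.e. tens of micrometres here)
  is fine for areas but was observed to shift bounding-box corners enough to
  break the half-open assignment of points lying exactly on grid lines, and
  to emit micrometre-wide sliver blocks where a polygon edge is tangent to a
  grid line. At $10^{-8}$ m the boolean-operation noise is several orders of
  magnitude below every tolerance in use.
* **Block existence**: a cell–area intersection below $10^{-9} d^2$
  (0.1 m² at 10 km cells) is treated as empty. Real coastal fragments are
  many orders of magnitude larger.
* **Shared boundaries** between cells are measured exactly by clipping the
  interface segment (an open path) against the area polygon, not by matching
  edges of clipped geometries.
* **Rounding**: scores are reported at 1 decimal place, the printed
  precision of the method's tables; classification operates on the rounded
  value, full precision is kept in `raw_total` and in the machine-readable
  report sidecar. Score conservation ($\sum_b S_b = \sum_i n_i w_i$ over
  in-area points) holds to $10^{-9}$ in double precision.
* **Coordinate systems**: a projected metric CRS is required; well-known
  geographic identifiers are rejected rather than silently reprojected,
  because a "10 km cell" has no meaning in degrees.

## The synthetic data generator

The institutional GIS layers behind the original assessment are not
published, so the package ships a generator that reproduces their *tabular*
structure: twelve layers whose default point counts are the published
per-layer pressure counts (34, 37, 28, 69, 164, 7, 770, 222, 10, 4, 22,
224 — 1591 points), scattered over either a rectangle (60 km × 55 km) or a
shipped synthetic coastal-peninsula polygon of ~3100 km² whose 10 km grid
yields full cells, undersized coastal fragments and (after merging) 31
blocks — the same order as the original 32. The peninsula outline is a
generated fixture, labelled as such; it is *not* the real coastline.

Two spatial processes are provided because the real clustering is unknown:
homogeneous rejection sampling, and a Thomas-like clustered process (uniform
parent centres, Gaussian isotropic offspring displacement, resampled into
the polygon). Per-layer point counts — and hence the per-layer totals
$n_i w_i$ and the whole-area score sum — are independent of the process;
*per-block* scores and the resulting class map are not, which is exactly the
behaviour the two processes let a user explore. Generation is deterministic
given one root seed, with per-layer substreams derived from (seed, layer
index) so that dropping or adding a layer leaves the others' coordinates
untouched.

What passing tests on synthetic data do show: the geometry, counting,
scoring, classification and allocation machinery is exact, conservative and
reproducible. What they do not show: anything about the real spatial
distribution of pressures, the appropriateness of the expert weights, or
the original per-block class map — those depend on unpublished data and on
judgment, not on code.

One statistical note: the uniformity sanity check (chi-square
goodness-of-fit of per-block counts against block areas) is asserted at the
*family* level over 20 fixed seeds — at most two rejections at
$\alpha = 0.01$ and an unremarkable median p-value — because a correct
uniform sampler fails an "every seed individually" reading about 18% of the
time.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the study's native scale: the
~3100 km² peninsula at 10 km cells (46 raw blocks, 31 after merging), 1591
simulated points per run, 20 seeded conservation runs across both area
shapes and both point processes, 10 seeded oracle runs of 2000 points
against a naive all-pairs point-in-polygon loop, and bytewise determinism
checks on the full report bundle. The whole suite runs in well under a
minute.

## Limitations

* Containment-only scoring: a large quarry straddling two blocks counts
  only where its representative point lies; there is no buffering or
  distance decay, by design.
* Facilities are points. Areal sources are one representative point each;
  if the upstream inventory lists multi-site companies per site, each site
  counts.
* The weights are inputs. The package validates them ($[0,1]$, unique
  names) but deliberately provides no machinery to fit or calibrate them.
* No reprojection. Inputs must already be in a projected metric CRS.
* Well placement modes are conveniences, not hydrogeology: no flow fields,
  no gradients, no optimisation.
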