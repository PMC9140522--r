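---
title: "Methods: from land cover to an ecological security pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from land cover to an ecological security pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecosecpat)
```

# Overview

`ecosecpat` implements the source–resistance–corridor workflow used to plan
ecological security patterns in fragmented, human-disturbed landscapes:
ecological **sources** are selected by morphological analysis plus graph
connectivity, a **resistance surface** expresses how hostile each cell is to
species movement, and **corridors** and **nodes** are extracted as
least-cost structures over that surface. This vignette records the model
definitions, the defaults and their rationale, the places where the design
was genuinely open and how we decided them, and what the synthetic test
landscapes do and do not demonstrate.

# MSPA segmentation

The ecological-land mask (water + vegetation) is segmented with 8-connected
foreground, a square structuring element of radius `edge_width` (Chebyshev
metric), and 4-connected background for the hole test. The complementary
connectivities avoid the topological paradox of a foreground ring and its
hole both being "connected" through the same diagonal.

The class definitions are normative in this package:

* **core**: Chebyshev distance to background > `edge_width` (the raster
  border counts as background, a conservative choice for patches touching
  the edge of the study area);
* **islet**: foreground components without core;
* **perforation / edge**: the band within `edge_width` of core; a band cell
  is perforation when its nearest background cell belongs to an interior
  hole, edge when it belongs to background connected to the border (ties go
  to edge);
* **bridge / loop / branch**: residual connector components, classified by
  how many distinct core components they reach through the band — two or
  more (bridge), one at two or more disjoint contact interfaces (loop), or
  one (branch).

This follows the published MSPA semantics but is not bit-compatible with
GUIDOS: near connector endpoints GUIDOS assigns contact-zone pixels with a
geodesic rule, whereas here every foreground cell within `edge_width` of a
core belongs to the boundary band. The default `edge_width` of 1 cell is
the conventional minimum edge width.

`class_statistics()` reports internally consistent percentages over the
foreground total, so the class shares always sum to 100.

# Patch graph and connectivity indices

Patches are 8-connected core components; pairwise distances are
**edge-to-edge** (minimum cell-centre distance), the standard convention
for these indices — centroid distances would punish large patches. Binary
links exist at ≤ 500 m, and the dispersal kernel is anchored so that a pair
exactly at the threshold disperses with probability 0.5:

$$p_{ij} = 0.5^{\,d_{ij}/500\,\mathrm{m}}.$$

IIC uses topological link counts; PC uses maximum-product path
probabilities computed as shortest paths on $-\log p$ over the complete
kernel graph. The complete graph matters: edge-to-edge distances violate
the triangle inequality, so a two-hop route through a large stepping-stone
patch can beat the direct kernel, and pairs beyond 500 m still contribute
to PC (only the binary links are thresholded).

Patch importance is the leave-one-out delta (in percent). Removal keeps the
surviving distance sub-matrix unchanged — no re-routing of distances
through the removed patch's cells, which matches how connectivity software
treats node removal. Sources are the top `k = 10` patches by dPC; dPC
ranking was preferred over plain core-area ranking because it is the more
specific criterion (area remains available through the ranking table). Ties
break by larger area, then lower patch id, so selection is deterministic.

# AHP weighting and the resistance surface

Factor weights come from a 6×6 pairwise judgment matrix over land use,
NDVI, slope, DEM, distance to road and distance to coal mine. The default
derivation is the **normalized row geometric mean**; the principal
eigenvector is available as an option. The two agree exactly on consistent
matrices and to ~1 % on the default matrix; the geometric mean is the
default because it reproduces the published reference weights to four
decimals. The consistency check uses
$\lambda_{\max} = \frac1n\sum_i (Aw)_i/w_i$, $CI = (\lambda_{\max}-n)/(n-1)$
and Saaty's classical RI table ($RI(6) = 1.24$); the default matrix yields
$CR = 0.0810 < 0.1$ (0.0823 with the eigenvector method).

Reclassification maps each factor to relative resistances on a 1–500
scale with half-open bands $[lo, hi)$. Two details are deliberate:

* the top NDVI band is closed at 1 ($[0.8, 1]$) so the NDVI domain is fully
  covered;
* the land-use table assigns the *other* class the same resistance as
  unused land (200). The reference scheme tabulates only five land-use
  classes; in an arid matrix "other types of land" are functionally bare
  ground, so inheriting the unused value is the least-surprising completion
  and keeps every generated scene reclassifiable.

The overlay $R = \sum_f w_f r_f$ is a convex combination, so the surface is
bounded by the per-factor band values — with the default scheme roughly
[1, 500], and in practice far narrower. A scene with no roads (or mines)
has no feature to measure distance from; those factors then fall in the
farthest, lowest-resistance band everywhere.

# Minimum cumulative resistance, corridors, ridgelines, nodes

The abstract minimum-cumulative-resistance model is operationalized as
multi-source Dijkstra on the 8-neighbour lattice with move cost
$(R_a + R_b)/2 \cdot L$, $L = 1$ orthogonal and $\sqrt 2$ diagonal (cell
units) — the convention of GIS cost-distance tools. Backlinks store, per
cell, the first predecessor direction (fixed clockwise scan from east) that
attains the optimal cost, which makes traced paths bit-reproducible.

Corridors are least-cost paths for all $k(k-1)/2$ unordered source pairs.
"Redundant" is made precise by a greedy rule: paths are processed in
ascending cost order and a path is dropped when more than `prune_overlap`
(default 0.8) of its cells already lie in the union of retained paths *or
inside any source patch*. Counting source-patch cells as covered means a
long A–C path that merely concatenates A–B and B–C through patch B is
recognized as fully redundant. `prune_overlap > 1` disables pruning. The
threshold is exposed rather than fixed because no published rule pins it
down.

Ridgelines use D8 routing (steepest descent among eight neighbours, ties to
the first direction in the clockwise order starting east) with flow
accumulation; ridge cells have zero accumulation. Single-cell pits are left
as local sinks: they receive their neighbours' inflow and therefore never
become ridges, whereas raising a pit to its lowest neighbour would flatten
that inflow and mark every enclosed minimum — the bottom of a bowl — as a
ridge, which contradicts the definition's intent. A perfectly flat DEM has
no flow at all; every cell then has zero accumulation and the function
warns about the degenerate result. An inverted-DEM stream extraction would
be an alternative reading of "ridgeline"; the zero-accumulation definition
was chosen because it needs no channelization threshold.

Ecological nodes default to corridor ∩ ridgeline cells, merged to their
centroid within a 3-cell Chebyshev radius; corridor–corridor crossings can
be added as candidates with `include_crossings = TRUE`. The intersection
reading was preferred because crossings of least-cost paths between the
same source set are frequent and mostly trivial (shared sub-paths), while
ridge crossings mark watershed passes — the functional weak points the
node concept targets.

# The synthetic landscape generator

The generator emulates the statistical structure the analysis assumes, not
any particular region: a dry matrix in which unused + other land covers
95 % of the area by default (water 0.5 %, vegetation 3 %, construction
1 %, coal mine 0.5 %), with cover drawn by thresholding a Gaussian random
field (correlation length `patchiness = 8` cells, i.e. 80 m at the 10 m
default cell size) at the rank quantiles of the target fractions. Ordering
the classes water → vegetation → unused along the field value gives the
moisture-like zonation that makes vegetation ring water bodies and form
compact patches — the geometry MSPA and the corridor model need. Realized
class counts match the targets to within one cell by construction.

NDVI is drawn per class (vegetation mean 0.5, water −0.3, everything else
0.05, sd 0.05, clipped to [−1, 1]), consistent with vegetated cells showing
high positive NDVI and water negative values. Terrain is a smoothed field
scaled to `relief_amplitude` (default 150 m over a 200 m base, gentle
desert-steppe relief) plus a 30 % regional west–east gradient so relief
scales exactly linearly with the amplitude. Roads are two-segment random
polylines crossing the scene, rasterized 8-connectedly; mines are point
cells drawn away from water; both are burned into the land cover
(construction / coal-mine codes) so the reclassification tables see
consistent inputs. Every stage seeds its RNG from the master seed plus a
fixed offset, so a scene is a pure function of its parameters.

What the generator does **not** emulate: radiometric noise and mixed
pixels, classification error, anisotropic or valley-following vegetation,
road networks with junction topology, temporal change (generate two scenes
with different seeds to mimic two dates). Passing tests on these scenes
therefore demonstrates algorithmic correctness and reproducibility, not
calibration to any real region.

# Numerical choices and problem sizes

* Reciprocity of judgment matrices is enforced to 1e-9; weights sum to 1
  within 1e-6.
* Cost-distance backlink reconstruction accepts a predecessor within
  relative 1e-9 of the Dijkstra optimum; path costs are checked against
  their move-cost sums at 1e-6.
* All tie-breaks (neighbour scan order, destination choice, component
  numbering, source ranking) are fixed and documented, so every output is
  bit-reproducible under a fixed seed.
* The test suite exercises exhaustive oracles where they are feasible:
  brute-force distance transforms at 30×30, path enumeration on patch
  graphs with ≤ 7 patches, Bellman–Ford on 20×20 resistance grids, and
  segmentation properties on hundreds of random 12–20-cell rasters. The
  end-to-end determinism check runs the full pipeline twice on a 300×300
  scene — small enough to iterate comfortably, large enough to produce
  tens of patches, corridors and nodes.

# Known limitations

* MSPA is not GUIDOS-bit-compatible (documented contact-zone difference),
  and grayscale or multi-scale MSPA is out of scope.
* dPC is reported whole; the intra/flux/connector decomposition is not
  implemented.
* The corridor model is least-cost-path only — no circuit-theory spread,
  no corridor width buffering.
* GeoTIFF support covers the package's own single-band, uncompressed
  little-endian layout (float64/int32) with pixel-scale, tiepoint and
  nodata tags; compressed or tiled GeoTIFFs from other software should be
  converted to ASCII grids first.
* No reprojection or resampling: all layers must share one grid, and the
  package checks but never fixes alignment.
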