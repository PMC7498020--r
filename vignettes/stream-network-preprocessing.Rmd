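---
title: "Deriving spatial stream-network data from elevation models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving spatial stream-network data from elevation models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamprep)
```

## The problem

Spatial stream-network (SSN) models describe autocorrelation among
measurements on a branching river network using covariances defined along
the network (flow-connected and flow-unconnected relationships), not
straight-line distance. Fitting them requires a dataset with strict
topological guarantees: a forest of in-trees with a single outflow per
network, no diverging nodes, no confluence receiving more than two inflows,
every site located *on* an edge with a known relative position, and
per-network tree tables linking each edge to its place in the hierarchy.
Real vector hydrography rarely satisfies this; a network derived from a
digital elevation model (DEM) satisfies most of it by construction, because
single-direction flow routing cannot braid or diverge. This package
implements that derivation end to end, plus the site and predictor
bookkeeping SSN software expects.

## Model and algorithms

### DEM conditioning

Depressions are removed by priority-flood: a min-heap is seeded with all
boundary cells (and cells adjacent to nodata, which is treated as off-grid),
then cells are popped in elevation order and each unvisited neighbour is
raised to at least `popped + eps` before being pushed. With
`eps = 1e-5` m/step, flats acquire a well-defined drainage direction while
the distortion stays far below any realistic elevation precision; a 1000-cell
flat accumulates only 1 cm of artificial gradient. The fill is idempotent
and never lowers a cell. This is a deliberate divergence from GIS backends
that route through depressions by least-cost search: priority-flood is
deterministic and order-independent, which the test suite relies on.

Optional stream burning lowers every cell crossed by a mapped channel
polyline by a fixed `burn_depth`. A cell is burned if the line intersects
its square (all-touched supercover traversal), not merely if its centre is
within half a cell of the line — the supercover guarantees the burned
channel is connected cell-to-cell, so the derived stream cannot jump the
channel between two diagonally adjacent burned cells. No default burn depth
is offered: the right value depends on local relief relative to the
vertical error of the channel map, so it is a mandatory argument where
burning is requested.

### Flow routing and accumulation

D8 assigns each cell to the steepest-descent neighbour of eight, slopes
computed as drop divided by centre distance (`cell_size` cardinal,
`cell_size·√2` diagonal). Ties are broken by the fixed neighbour order E,
SE, S, SW, W, NW, N, NE — first match wins — so results are reproducible
across platforms. MFD (Freeman scheme) spreads outflow over all strictly
lower neighbours with weights proportional to `slope^1.1`; the exponent is
the customary Freeman value and is exposed as an argument. Accumulation
processes cells in decreasing filled elevation, a valid topological order
because flow always descends strictly after filling; D8 accumulation is
integer-valued, MFD conserves mass to floating-point rounding (the tests
require `1e-6` relative).

Stream extraction may use either routing (default MFD, the more physical
choice for accumulation), but catchments and reach contributing areas
(RCAs) are always delineated on D8. This is deliberate: SSN attribution
needs *disjoint* cell sets whose areas add exactly along the tree
(`h2o = rca + Σ upstream h2o`), and only single-direction routing yields
crisp, additive partitions. The cost is that a site's "exact" catchment is
a D8 catchment even when the stream raster came from MFD accumulation.

### Network topology

Stream cells (`accumulation ≥ accum_threshold`) are partitioned into
segments between breakpoints; a junction cell belongs to the segment
downstream of it, so inflowing edges end at the junction cell centre.
Headwater segments shorter than `min_stream_length` cells are removed and
the labelling repeated until stable — removing a spur can turn a confluence
into a pass-through, which then merges its two segments. On synthetic
valley terrain this pruning is also what removes the "herringbone" of
lateral hillslope chains that reach the accumulation threshold without
being streams in any meaningful sense.

Each confluence with `k ≥ 3` inflows is repaired by repeatedly taking the
two smallest-rid inflows, moving their junction to a pseudo node placed
`offset_fraction · cell_size` (default 0.25, valid range (0, 0.5]) upstream
*along the smallest-rid inflow's geometry*, and inserting an artificial
edge from the pseudo node to the old node. The choice of which inflows to
move is not fixed by the SSN format; smallest-rid-first is deterministic
and independent of processing order. The artificial edge carries an empty
RCA — its stub area physically lies inside the old junction cell — which is
what keeps catchment areas conserved exactly through the correction. The
second (larger-rid) reconnected inflow has its final vertex moved to the
pseudo node, changing its length by at most the offset; if the smallest-rid
inflow is shorter than the offset, the stub is shortened to half that
edge's length. A `k`-inflow node gains exactly `k − 2` artificial edges.

binaryIDs encode tree position: the outlet edge is `"1"`; at each
confluence the upstream edge with the larger cumulative catchment appends
`"1"`, the other `"0"` (ties to the smaller rid); a single upstream edge —
possible after lake severing — appends `"1"`. `upDist` of an edge is the
along-network distance from the outlet to the edge's *upstream* node
(outlet edge: its own length; recursively `upDist(e) = upDist(downstream) +
length(e)`), and a site's `upDist` is
`upDist(edge) − (1 − ratio)·length(edge)` with `ratio` measured from the
downstream junction. The format itself does not dictate these two
conventions; they are fixed here, stated prominently, and used consistently
by the export and the attribution formulas.

Severing at lakes removes every edge whose geometry intersects a lake
polygon. Each remaining in-tree rooted at an edge that lost its downstream
edge becomes its own network: if a confluence's outflow is deleted, its two
inflows become two separate one-outlet networks whose outlet points
coincide — the admissibility census therefore judges converging/complex
nodes within each network, not globally. Surviving networks keep their
netID; severed roots get fresh ids in outlet-coordinate order; removed rids
are retired.

### Site attribution

Edge summaries are computed per predictor layer over the RCA and, by
upstream aggregation, over the edge catchment. Sites inherit them by linear
interpolation along the edge: for any additive quantity
`approx(site) = cum(edge) − ratio · rca(edge)`. At `ratio = 0` this is the
downstream-node catchment; at `ratio = 1` it is the sum over upstream
edges; both endpoints are forced by the definition and unit-tested. The
interpolation rule between the endpoints is a design choice (the RCA is
apportioned linearly in `ratio`), and its error for any additive quantity
is bounded by the edge's RCA — an invariant the tests assert on every
fixture site.

The exact method delineates each site's own catchment with
`upstream_cells()`. The catchment seed is the stream cell *of the site's
edge* containing the snapped point; if the containing cell is not one of
that edge's cells (which happens exactly when the site sits at the
downstream junction, whose cell belongs to the downstream segment, or on a
cell-boundary rounding), the nearest cell of the edge's own path is used
instead. Seeding off the edge's own path would let a ratio≈0 site swallow
its sibling tributary's catchment, violating both the RCA error bound and
the endpoint identity; seeding on the path keeps the site catchment nested
between `cum − rca` and `cum`. Sites are never attributed on artificial
edges — snapping considers only real edges.

Percent and mean summaries are recomputed from interpolated sums and
interpolated cell counts; nodata cells are excluded from both numerator and
denominator. Polygon predictors are rasterised cell-centre-in-polygon at
DEM resolution before any summarisation, so raster and vector inputs give
identical areas by construction.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `accum_threshold` | cells | 20 (pipeline) | channel initiation; tune to minimise snap distances |
| `min_stream_length` | cells | 10–15 (pipeline) | prunes sub-threshold headwater spurs; also removes lateral artefacts on smooth synthetic relief |
| `eps` (fill) | m/step | 1e-5 | resolves flats; negligible vs. DEM precision |
| MFD exponent | – | 1.1 | Freeman's value; larger → more convergent |
| `offset_fraction` | cell fraction | 0.25 | stub length for confluence repair; (0, 0.5] keeps the pseudo node inside the inflow's last cell |
| `max_dist` (snap) | m | user | sites moved farther are deleted and reported; large values hide network-resolution problems |
| prediction spacing | m | user | sites at `s/2 + k·s` from the outlet, so none falls on the outlet node |

## What the synthetic worlds do and do not establish

The fixture generator produces three relief families: a strictly monotone
tilted plane (single outlet, no confluences — the degenerate control), a
multi-valley surface (elevation = along-channel distance to the outlet plus
a steep cross-valley parabola; two valleys give a guaranteed Y, three
valleys converge on one junction cell and guarantee a complex confluence at
coarse thresholds), and low-pass-filtered Gaussian noise over a tilt. The
valley geometry was calibrated once so that `accum_threshold = 20` with
`min_stream_length = 15` on a 60×60, 10 m grid yields a single-digit edge
count. Sites are sampled uniformly along edges with their true `(rid,
ratio)` recorded, then jittered with Gaussian noise, so snapping can be
scored against truth. Land use is a seeded mosaic of axis-aligned
rectangles — not the Voronoi patches a naturalistic generator might use —
because the polygon layer must be provably cell-identical to its raster
form to cross-check the two predictor paths, and rectangle mosaics make
that exact while exercising the same generic point-in-polygon rasteriser.

A green suite on these worlds establishes the algebra: conservation,
additivity, admissibility, encoding, round-trips, error bounds. It does
*not* establish realism — no DEM noise model, no braided or anthropogenic
channels, no CRS handling (all inputs must share one projected metric CRS),
and flat lowland DEMs where relief is below sensor noise will still produce
arbitrary (though deterministic) drainage, as all routing algorithms do.

## Numerical and degenerate-input choices

* Tie-breaks everywhere are by fixed neighbour order or smallest rid; no
  randomness outside the seeded fixture generator.
* A single-cell outlet segment would have a zero-length, self-looping
  geometry; its edge is extended half a cell toward its off-grid exit so
  every edge has positive length and distinct end nodes.
* Equidistant snapping candidates resolve to the smaller rid
  (`1e-12` m comparison tolerance).
* Prediction-site counts: with branching, both branches above a confluence
  continue the same `s/2 + k·s` distance sequence, so "consecutive sites
  along any unbranched path differ by exactly `s`" holds everywhere, but
  the total count equals `length/s` only on unbranched networks (it is
  honoured exactly there and tested so); on branched networks the count
  depends on how branch lengths fall against the phase.
* DBF numerics are written with fixed formats (integers width 10, doubles
  width 19 with 8 decimals) and a fixed header date, so
  export→read→export is byte-identical, not merely value-identical.

## Limitations

GeoTIFF input is not supported (no raster driver exists in the dependency
envelope; ESRI ASCII grids are the interchange format). The shapefile
writer covers exactly what `.ssn` consumers need (2D points, single-part
polylines, C/N fields). SSN model fitting, hydrologic distance matrices,
reprojection, time-varying predictors and interactive network editing are
out of scope.
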