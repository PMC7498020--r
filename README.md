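# streamprep

Measurements taken at monitoring sites along the same stream are not
statistically independent: water, solutes and organisms move downstream, so
sites connected by flow share variation that Euclidean-distance spatial
models mis-describe. Spatial stream-network (SSN) models fix this with
covariance functions defined on the branching network itself — but they need
the network, the sites and their predictors delivered in a rigid,
topologically clean format (the `.ssn` directory). Producing that input
normally requires a GIS stack.

`streamprep` builds the whole `.ssn` input from scratch in R, with **no
external GIS**: it derives the stream network from a digital elevation model
(DEM), cleans its topology, delineates reach contributing areas and
catchments, snaps sampling sites, attaches predictor summaries and writes a
validated `.ssn` directory. It is aimed at freshwater ecologists and
hydrologists preparing monitoring data for SSN-style spatial regression.

## What it computes

* **DEM conditioning** — optional *stream burning* (lowering elevations by a
  fixed depth along a mapped channel network to guide the derived streams)
  and *priority-flood depression filling* with an epsilon gradient
  (1e-5 m/step), so every cell has a strictly descending path off the grid.
* **Flow routing** — D8 (each cell drains to its steepest-descent neighbour
  of eight, diagonal distance honoured) and Freeman multiple-flow-direction
  (MFD) routing, where outflow to each lower neighbour is proportional to
  *slope*^1.1. Flow accumulation *A(c)* counts (or, for MFD,
  fraction-weights) all cells draining through *c*, including *c* itself.
* **Network extraction** — cells with *A(c) ≥ accum_threshold* become stream
  cells; headwater segments shorter than `min_stream_length` cells are
  pruned iteratively; segments between sources, confluences and outlets
  become directed edges. Each edge carries its *reach contributing area*
  (RCA: the cells draining laterally into it and into no upstream edge) and
  cumulative catchment area, with the exact invariant
  `h2o(e) = rca(e) + Σ h2o(upstream edges)` — RCA cell sets are disjoint, so
  areas are additive to machine precision.
* **Topology repair** — SSN models reject *complex confluences* (≥ 3
  inflows to one node). `correct_complex_confluences()` moves the junction
  of the two smallest-rid inflows a quarter cell upstream onto a new pseudo
  node and inserts a tiny artificial zero-RCA edge, repeating until every
  confluence has exactly two inflows (a *k*-inflow node gains exactly
  *k − 2* artificial edges). Networks can also be severed at lake polygons.
* **Tree encoding** — every network gets `binaryID`s: the outlet edge is
  `"1"` and each upstream edge appends one character, so an edge's ID is a
  prefix of every edge upstream of it; `upDist` is the along-network
  distance from the outlet, Shreve magnitude counts headwater sources.
* **Sites** — observation points snap to the nearest edge (points farther
  than `max_dist` are dropped and reported); each site gets `ratio` (its
  position along the edge measured from the downstream junction), `upDist`,
  and the snap distance `dist`. Prediction sites are laid out at constant
  along-network spacing, phase s/2 from the outlet. Repeated measurements
  expand to one record per measurement sharing a `locID`.
* **Predictor attribution** — layers (continuous rasters, or categorical
  rasters/polygon mosaics) are summarised per edge over RCA and catchment;
  sites inherit them either *approximately* — linear interpolation
  `cum(edge) − ratio · rca(edge)` along the edge — or *exactly*, by
  delineating each site's own D8 catchment. The approximation error of any
  additive quantity is bounded by the edge's RCA.
* **Export** — `edges.shp`, `sites.shp`, `preds.shp` (a built-in minimal
  shapefile writer/reader) plus one `netID<k>.dat` topology table
  (`"rid","binaryID"`) per network; `read_ssn()` re-reads and validates the
  bundle (round-trip is a fixed point; inadmissible topologies are
  rejected with named nodes).

A seeded fixture generator (`fixture_spec()`, `make_dem()`, `make_sites()`,
`make_landuse()`) produces drainable synthetic terrain (tilted plane,
multi-valley, smoothed noise), jittered sites with known true positions and
a land-use mosaic in exactly consistent raster and polygon form — the whole
pipeline is testable offline.

## Worked example

```r
library(streamprep)

spec <- fixture_spec(nrows = 60, ncols = 60, relief = "twin_valley",
                     n_valleys = 3, seed = 42)          # three valleys -> complex confluence
demf <- fill_depressions(make_dem(spec))
fd   <- mfd_directions(demf)
net  <- vectorize(extract_streams(accumulate(fd, "mfd"), fd,
                                  accum_threshold = 20, min_stream_length = 15),
                  fd, demf)
check_complex_confluences(net)
#> [1] 3                                  # one 3-inflow node
net <- correct_complex_confluences(net)
net
#> <stream_network> 5 edges, 6 nodes, 1 network(s)
#>   total length 1444.1 m, outlet catchment(s) 0.3600 km2
net$edges[, c("rid", "binaryID", "length_m", "upDist_m", "rca_km2", "h2o_km2", "artificial")]
#>   rid binaryID length_m upDist_m rca_km2 h2o_km2 artificial
#> 1   0      111    430.3    652.8  0.1014  0.1014      FALSE
#> 2   1      110    358.4    580.9  0.0381  0.0381      FALSE
#> 3   2        1    220.0    220.0  0.1145  0.3600      FALSE
#> 4   3       10    432.8    652.8  0.1060  0.1060      FALSE
#> 5   4       11      2.5    222.5  0.0000  0.1395       TRUE
```

The three valley edges and the trunk survive; rid 4 is the 2.5 m artificial
stub inserted by the correction (0.25 × the 10 m cell size), carrying no
RCA — so the outlet catchment (0.36 km², the full 60×60×100 m² grid) is
conserved exactly: 0.1014 + 0.0381 + 0.1145 + 0.1060 + 0 = 0.3600.

```r
sites <- snap_sites(make_sites(spec, net), net, max_dist = 150)$sites
head(sites[, c("pid", "rid", "ratio", "upDist_m", "dist_moved")], 3)
#>   pid rid  ratio upDist_m dist_moved
#> 1   1   1 0.3563    350.2     0.2794
#> 2   2   3 0.6041    481.5     2.6640
#> 3   3   0 0.6305    493.8     3.9508

lu  <- make_landuse(spec, demf)
lay <- predictor_layer("lu", grid = lu$raster, kind = "categorical", stats = "area_km2")
net   <- attach_edge_attributes(net, lay)
sites <- sites_attributes_exact(sites_attributes_approx(sites, net, lay),
                                fd, lay, demf, net)
head(sites[, c("pid", "H2OArea_avg", "H2OArea_exact", "lu_1_km2_avg", "lu_1_km2_exact")], 3)
#>   pid H2OArea_avg H2OArea_exact lu_1_km2_avg lu_1_km2_exact
#> 1   1      0.0245        0.0329      0.01918         0.0249
#> 2   2      0.0420        0.0425      0.00143         0.0000
#> 3   3      0.0375        0.0386      0.03007         0.0386
cor(sites$H2OArea_avg, sites$H2OArea_exact)
#> [1] 0.994544

export_ssn(net, sites, generate_prediction_sites(net, spacing_m = 150),
           "out.ssn", overwrite = TRUE)
str(read_ssn("out.ssn"), max.level = 1)   # re-read + full validation
```

`H2OArea_avg` is the interpolated (approximate) catchment area of each site,
`H2OArea_exact` its exact per-site D8 catchment; on this fixture the two
agree with *r* = 0.995, and every absolute difference is bounded by the
host edge's RCA.

## Command line

```sh
streamprep fixtures --spec spec.json --out fixtures/   # write synthetic inputs
streamprep run --config config.json                    # DEM -> .ssn in one call
```

(`exec/streamprep` is installed with the package; the config keys are
documented in `?run_pipeline`.)

## File formats

Rasters are read/written as ESRI ASCII grids (GeoTIFF is not supported in
this build — convert with `gdal_translate -of AAIGrid` first). Vector
inputs (sites, burn streams, lakes, land-use polygons) are GeoJSON. `.ssn`
layers are shapefiles by default (`layer_format = "geojson"` as an
alternative dialect); DBF field names are abbreviated deterministically to
10 characters, with the map in `field_names.json`.
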