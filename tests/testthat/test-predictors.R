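# Predictor summarisation over RCAs/catchments and site attribution.

tv_attributed <- function() {
  cached("tv3_attributed", function() {
    tv <- tv_pipeline(n_valleys = 3)
    net <- correct_complex_confluences(tv$net)
    lu <- make_landuse(tv$spec, tv$demf)
    layers <- list(
      predictor_layer("lu", grid = lu$raster, kind = "categorical",
                      stats = c("percent", "area_km2")),
      predictor_layer("elev", grid = tv$demf, kind = "continuous",
                      stats = c("mean", "sum")))
    net <- attach_edge_attributes(net, layers)
    pts <- make_sites(fixture_spec(relief = "twin_valley", n_valleys = 3,
                                   seed = 5, n_sites = 25, site_jitter_m = 5), net)
    sites <- snap_sites(pts, net, 150)$sites
    sites <- sites_attributes_approx(sites, net, layers)
    sites <- sites_attributes_exact(sites, tv$fd, layers, tv$demf, net)
    list(tv = tv, net = net, layers = layers, sites = sites, lu = lu)
  })
}

test_that("edge attributes: uniform layer, percent definition, upstream-cells oracle", {
  tv <- tv_pipeline(n_valleys = 2)
  unif <- raster_grid(matrix(7, 60, 60), cell_size = 10, origin_y = 600)
  lay <- predictor_layer("u", grid = unif, kind = "continuous", stats = c("mean", "sum"))
  net <- attach_edge_attributes(tv$net, lay)
  expect_equal(net$edges$u_mean_rca, rep(7, nrow(net$edges)))
  expect_equal(net$edges$u_mean_cum, rep(7, nrow(net$edges)))
  # sums aggregate: outlet cum sum = 7 * basin cell count
  out <- net$edges[net$edges$binaryID == "1", ]
  expect_equal(out$u_sum_cum, 7 * out$h2o_km2 / (10 * 10 / 1e6))

  ta <- tv_attributed()
  net3 <- ta$net; fd <- ta$tv$fd
  # categorical percent at the outlet equals the direct basin census
  out3 <- net3$edges[net3$edges$binaryID == "1", ]
  out_cell <- ta$net$cells[[as.character(out3$rid)]]
  basin <- upstream_cells(fd, out_cell[length(out_cell)])
  luv <- ta$lu$raster$values[basin]
  for (cl in sort(unique(as.vector(ta$lu$raster$values)))) {
    expect_equal(out3[[sprintf("lu_%d_pct_cum", cl)]],
                 100 * sum(luv == cl) / length(luv))
  }
  # continuous cum sum at the outlet equals direct summation over the basin
  expect_equal(out3$elev_sum_cum, sum(ta$tv$demf$values[basin]))
  # class percents partition: sum to 100 on every edge
  pct <- as.matrix(net3$edges[, grep("_pct_cum$", names(net3$edges))])
  expect_equal(unname(rowSums(pct)), rep(100, nrow(pct)), tolerance = 1e-9)
  expect_true(all(pct >= 0 & pct <= 100 + 1e-12))
  expect_error(attach_edge_attributes(net3, predictor_layer("bad",
    grid = raster_grid(matrix(1, 5, 5), 10), kind = "continuous")), "co-registered")
})

test_that("approximate attribution: endpoint identities and stated arithmetic", {
  ta <- tv_attributed()
  net <- ta$net
  e <- net$edges[!net$edges$artificial & net$edges$shreve == 1, ][1, ]
  g <- net$geoms[[as.character(e$rid)]]
  ends <- rbind(g[nrow(g), ], g[1, ])  # downstream junction, upstream source
  s <- snap_sites(data.frame(x = ends[, 1], y = ends[, 2]), net, 1)$sites
  s <- s[order(s$ratio), ]
  s <- sites_attributes_approx(s, net, ta$layers)
  i0 <- which(s$rid == e$rid & abs(s$ratio) < 1e-9)
  i1 <- which(s$rid == e$rid & abs(s$ratio - 1) < 1e-9)
  if (length(i0)) expect_equal(s$H2OArea_avg[i0], e$h2o_km2)            # ratio 0
  expect_true(length(i1) == 1)
  expect_equal(s$H2OArea_avg[i1], e$h2o_km2 - e$rca_km2, tolerance = 1e-12)  # ratio 1
  expect_equal(s$elev_sum_avg[i1],
               net$pred_sums$elev$tab$cum_sum[match(e$rid, net$pred_sums$elev$tab$rid)] -
                 net$pred_sums$elev$tab$rca_sum[match(e$rid, net$pred_sums$elev$tab$rid)],
               tolerance = 1e-9)

  # cum 10 km2, rca 2 km2, ratio 0.5 -> 9 km2 (the interpolation formula)
  fake <- s[1, ]
  fake$ratio <- 0.5
  net_fake <- net
  j <- match(fake$rid, net_fake$edges$rid)
  net_fake$edges$h2o_km2[j] <- 10
  net_fake$edges$rca_km2[j] <- 2
  expect_equal(sites_attributes_approx(fake, net_fake, list())$H2OArea_avg, 9)
})

test_that("exact attribution: nesting bound, uniform layer, outlet identity, correlation", {
  ta <- tv_attributed()
  s <- ta$sites
  net <- ta$net
  ei <- match(s$rid, net$edges$rid)
  # |approx - exact| <= rca(edge), for area and for class areas
  expect_true(all(abs(s$H2OArea_avg - s$H2OArea_exact) <= net$edges$rca_km2[ei] + 1e-12))
  for (cl in ta$net$pred_sums$lu$classes) {
    a <- s[[sprintf("lu_%d_km2_avg", cl)]]
    x <- s[[sprintf("lu_%d_km2_exact", cl)]]
    expect_true(all(abs(a - x) <= net$edges$rca_km2[ei] + 1e-12))
  }
  # approx-vs-exact catchment area correlate strongly (>= 20 sites)
  expect_gte(nrow(s), 20)
  expect_gt(stats::cor(s$H2OArea_avg, s$H2OArea_exact), 0.95)

  # exact equals approx at ratio = 0 (same cell sets on a D8 network)
  e <- net$edges[net$edges$shreve == 1 & !net$edges$artificial, ][1, ]
  g <- net$geoms[[as.character(e$rid)]]
  p <- g[nrow(g), ]
  s0 <- snap_sites(data.frame(x = p[1], y = p[2]), net, 1)$sites
  s0 <- s0[s0$rid == e$rid, , drop = FALSE]
  if (nrow(s0)) {
    s0 <- sites_attributes_exact(sites_attributes_approx(s0, net, ta$layers),
                                 ta$tv$fd, ta$layers, ta$tv$demf, net)
    expect_equal(s0$H2OArea_exact, s0$H2OArea_avg, tolerance = 1e-12)
  }
  # a site at the network outlet has the whole basin as its exact catchment
  out <- net$edges[net$edges$binaryID == "1", ]
  go <- net$geoms[[as.character(out$rid)]]
  po <- go[nrow(go), ]
  so <- snap_sites(data.frame(x = po[1], y = po[2]), net, 1)$sites
  so <- sites_attributes_exact(so, ta$tv$fd, list(), ta$tv$demf, net)
  cells_out <- net$cells[[as.character(out$rid)]]
  basin <- upstream_cells(ta$tv$fd, cells_out[length(cells_out)])
  expect_equal(so$H2OArea_exact, length(basin) * 1e-4)

  # uniform layer: exact mean equals the layer value for every site
  unif <- predictor_layer("u", grid = raster_grid(matrix(3.5, 60, 60), 10, origin_y = 600),
                          kind = "continuous", stats = "mean")
  su <- sites_attributes_exact(s[1:5, ], ta$tv$fd, unif, ta$tv$demf, net)
  expect_equal(su$u_mean_exact, rep(3.5, 5))
})

test_that("raster and polygon predictor paths agree exactly; aggregation is order-independent", {
  ta <- tv_attributed()
  net <- ta$net
  poly_layer <- predictor_layer("lu", polygons = ta$lu$polygons, classes = ta$lu$classes,
                                kind = "categorical", stats = c("percent", "area_km2"))
  net_poly <- attach_edge_attributes(ta$net, poly_layer)
  for (cn in grep("^lu_", names(net$edges), value = TRUE)) {
    expect_equal(net_poly$edges[[cn]], net$edges[[cn]], tolerance = 1e-12)
  }
  # order independence: recursive per-edge direct summation over the
  # catchment equals the upstream aggregation
  fd <- ta$tv$fd
  luv <- as.numeric(ta$lu$raster$values)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    cells_e <- net$cells[[as.character(e$rid)]]
    if (!length(cells_e)) next
    basin <- upstream_cells(fd, cells_e[length(cells_e)])
    cl1 <- net$pred_sums$lu$classes[1]
    expect_equal(e[[sprintf("lu_%d_km2_cum", cl1)]],
                 sum(luv[basin] == cl1) * 1e-4, tolerance = 1e-12)
  }
})
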