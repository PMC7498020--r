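# Snapping, prediction sites, measurement merging.

test_that("snap_sites: identity on-edge, max_dist dropping, brute-force nearest", {
  tv <- tv_pipeline(n_valleys = 2)
  net <- tv$net
  # a point exactly on an edge stays put
  g <- net$geoms[[as.character(net$edges$rid[1])]]
  on_edge <- streamprep:::polyline_point_at(g, net$edges$length_m[1] * 0.37)
  r <- snap_sites(data.frame(x = on_edge[1], y = on_edge[2]), net, 150)
  expect_equal(r$sites$dist_moved, 0, tolerance = 1e-9)
  expect_equal(r$sites$x, on_edge[1], tolerance = 1e-9)
  expect_equal(r$sites$rid, net$edges$rid[1])

  # 151 m perpendicular offset with max_dist 150 is dropped, 149 kept
  out_e <- net$edges[net$edges$binaryID == "1", ]
  go <- net$geoms[[as.character(out_e$rid)]]
  base <- streamprep:::polyline_point_at(go, out_e$length_m / 2)
  pts <- data.frame(x = base[1] + c(151, 149), y = base[2])  # offset due E of the N-S trunk
  r2 <- snap_sites(pts, net, 150)
  expect_equal(r2$dropped, 1L)
  expect_equal(nrow(r2$sites), 1L)
  expect_equal(r2$sites$dist_moved, 149, tolerance = 1e-6)
  expect_equal(nrow(r2$sites) + length(r2$dropped), nrow(pts))

  # nearest-edge choice equals exhaustive minimisation over all segments
  set.seed(5)
  rnd <- data.frame(x = runif(15, 0, 600), y = runif(15, 0, 600))
  r3 <- snap_sites(rnd, net, 1e9)
  for (i in seq_len(15)) {
    dmin <- Inf; rid_min <- NA
    for (j in seq_len(nrow(net$edges))) {
      gg <- net$geoms[[as.character(net$edges$rid[j])]]
      for (k in seq_len(nrow(gg) - 1)) {
        np <- streamprep:::nearest_on_segment(rnd$x[i], rnd$y[i],
                                              gg[k, 1], gg[k, 2], gg[k + 1, 1], gg[k + 1, 2])
        d <- sqrt((rnd$x[i] - np[1])^2 + (rnd$y[i] - np[2])^2)
        if (d < dmin - 1e-12) { dmin <- d; rid_min <- net$edges$rid[j] }
      }
    }
    expect_equal(r3$sites$dist_moved[i], dmin, tolerance = 1e-9)
    expect_equal(r3$sites$rid[i], rid_min)
  }
  expect_error(snap_sites(rnd, net, -1), "max_dist")
})

test_that("snapped positional attributes respect the ratio/upDist conventions", {
  tv <- tv_pipeline(n_valleys = 2)
  net <- tv$net
  e <- net$edges[net$edges$binaryID == "10", ]
  g <- net$geoms[[as.character(e$rid)]]
  # place at the downstream junction: ratio 0, upDist = junction distance
  p0 <- g[nrow(g), ]
  # and at 25% arc from the upstream end: ratio 0.75
  p1 <- streamprep:::polyline_point_at(g, 0.25 * e$length_m)
  r <- snap_sites(data.frame(x = c(p0[1], p1[1]), y = c(p0[2], p1[2])), net, 10)
  i <- which(r$sites$rid == e$rid)
  expect_true(length(i) >= 1)
  expect_equal(r$sites$ratio[r$sites$dist_moved == 0 & r$sites$ratio > 0.5][1], 0.75,
               tolerance = 1e-9)
  ratio <- r$sites$ratio
  expect_true(all(ratio >= 0 & ratio <= 1))
  expect_equal(r$sites$upDist_m,
               net$edges$upDist_m[match(r$sites$rid, net$edges$rid)] -
                 net$edges$length_m[match(r$sites$rid, net$edges$rid)] * (1 - ratio),
               tolerance = 1e-9)
  # zero-jitter fixture sites recover the exact truth
  spec0 <- fixture_spec(relief = "twin_valley", n_valleys = 2, seed = 9,
                        n_sites = 15, site_jitter_m = 0)
  pts <- make_sites(spec0, net)
  r0 <- snap_sites(pts, net, 150)
  expect_equal(length(r0$dropped), 0L)
  expect_equal(r0$sites$rid, pts$true_rid)
  expect_equal(r0$sites$ratio, pts$true_ratio, tolerance = 1e-9)
  expect_lt(max(r0$sites$dist_moved), 1e-9)
  expect_equal(r0$sites$pid, r0$sites$locID)
  expect_false(anyDuplicated(r0$sites$pid) > 0)
})

test_that("sites snapped to artificial stubs are re-snapped to real edges", {
  fixed <- correct_complex_confluences(tv_pipeline(n_valleys = 3)$net)
  stub <- fixed$edges[fixed$edges$artificial, ]
  g <- fixed$geoms[[as.character(stub$rid)]]
  mid <- streamprep:::polyline_point_at(g, stub$length_m / 2)
  r <- snap_sites(data.frame(x = mid[1], y = mid[2]), fixed, 50)
  expect_false(r$sites$rid %in% fixed$edges$rid[fixed$edges$artificial])
})

test_that("prediction sites: spacing arithmetic, counts, constant gaps", {
  # single 1000 m edge, spacing 250 -> 4 sites at 125, 375, 625, 875
  chain <- raster_grid(matrix(seq(200, 100, length.out = 101), nrow = 1), cell_size = 10)
  fd <- d8_directions(chain)
  net1 <- vectorize(extract_streams(accumulate(fd, "d8"), fd, 1), fd, chain)
  expect_equal(net1$edges$length_m, 1000)
  ps <- generate_prediction_sites(net1, spacing_m = 250)
  expect_equal(nrow(ps), 4)
  expect_equal(ps$upDist_m, c(125, 375, 625, 875), tolerance = 1e-9)
  expect_true(all(ps$dist_moved == 0))
  # n_sites honoured when the spacing divides the length
  ps8 <- generate_prediction_sites(net1, n_sites = 8)
  expect_equal(nrow(ps8), 8)
  expect_equal(diff(ps8$upDist_m), rep(125, 7), tolerance = 1e-9)

  # branched network: consecutive sites along any unbranched path differ by s
  tv <- tv_pipeline(n_valleys = 2)
  s <- 60
  pst <- generate_prediction_sites(tv$net, spacing_m = s)
  for (rid in tv$net$edges$rid) {
    d <- sort(pst$upDist_m[pst$rid == rid])
    if (length(d) > 1) expect_equal(diff(d), rep(s, length(d) - 1), tolerance = 1e-6)
  }
  # phase: every site distance is s/2 + k s from the outlet
  k <- (pst$upDist_m - s / 2) / s
  expect_equal(k, round(k), tolerance = 1e-9)
  expect_error(generate_prediction_sites(tv$net), "exactly one")
  expect_error(generate_prediction_sites(tv$net, n_sites = 3, spacing_m = 10), "exactly one")
  w <- capture_warnings(empty <- generate_prediction_sites(net1, spacing_m = 5000))
  expect_match(w, "exceeds", all = FALSE)
  expect_equal(nrow(empty), 0)   # zero sites allowed
})

test_that("merge_sites_with_measurements expands, preserves locID, renumbers pid", {
  tv <- tv_pipeline(n_valleys = 2)
  pts <- make_sites(fixture_spec(relief = "twin_valley", seed = 3, n_sites = 3,
                                 site_jitter_m = 2), tv$net)
  sites <- snap_sites(pts, tv$net, 150)$sites
  tab <- data.frame(locID = c(1, 2, 3), value = c(10, 20, 30))
  m1 <- merge_sites_with_measurements(sites, tab, "locID")
  expect_equal(nrow(m1), 3)
  expect_equal(m1$pid, 1:3)
  expect_equal(m1$value, c(10, 20, 30))

  tab4 <- data.frame(locID = c(2, 2, 2, 2), month = 1:4, conc = c(0.1, 0.2, 0.3, 0.4))
  m4 <- merge_sites_with_measurements(sites, tab4, "locID")
  expect_equal(nrow(m4), 4)
  expect_equal(unique(m4$locID), 2)
  expect_equal(m4$pid, 1:4)
  expect_equal(length(unique(m4$x)), 1)

  mixed <- rbind(tab, data.frame(locID = 99, value = -1))
  expect_warning(m5 <- merge_sites_with_measurements(sites, mixed, "locID"), "unmatched")
  expect_equal(nrow(m5), 3)   # record count = matched row count
  expect_error(merge_sites_with_measurements(sites, tab, "nope"), "missing")
})
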