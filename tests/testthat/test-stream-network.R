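# Stream extraction, vectorization, topology correction, lakes.

test_that("extract_streams thresholds and boundary cases", {
  chain <- raster_grid(matrix(c(4, 3, 2, 1, 0), nrow = 1), cell_size = 10)
  fd <- d8_directions(chain)
  acc <- accumulate(fd, "d8")
  st <- extract_streams(acc, fd, 3)
  expect_equal(which(st$values > 0), 3:5)
  st_all <- extract_streams(acc, fd, 5)   # threshold = total cells: outlet only
  expect_equal(which(st_all$values > 0), 5L)
  expect_error(extract_streams(acc, fd, 6), "no streams")
})

test_that("pruning removes short headwater spurs iteratively but keeps long ones", {
  dem <- spur_dem(spur1 = 3, spur2 = 5)
  fd <- d8_directions(dem)
  acc <- accumulate(fd, "d8")
  unpruned <- vectorize(extract_streams(acc, fd, 1, 0), fd, dem)
  expect_equal(nrow(unpruned$edges), 5)   # main split at 2 junctions + 2 spurs
  pruned <- vectorize(extract_streams(acc, fd, 1, 4), fd, dem)
  # 3-cell spur gone; its junction merged away; 5-cell spur kept
  expect_equal(nrow(pruned$edges), 3)
  lens <- vapply(pruned$edges$rid, function(r) length(pruned$cells[[as.character(r)]]), integer(1))
  expect_true(any(lens == 5))             # the surviving spur
  # pruning everything shorter than any headwater leaves the trunk only
  trunk_only <- vectorize(extract_streams(acc, fd, 1, 6), fd, dem)
  expect_equal(nrow(trunk_only$edges), 1)
})

test_that("vectorize: single stream, Y network, two disjoint basins", {
  chain <- raster_grid(matrix(seq(50, 10, length.out = 9), nrow = 1), cell_size = 10)
  fd <- d8_directions(chain)
  net1 <- vectorize(extract_streams(accumulate(fd, "d8"), fd, 1), fd, chain)
  expect_equal(nrow(net1$edges), 1)
  expect_equal(net1$edges$binaryID, "1")
  expect_equal(net1$edges$shreve, 1L)
  expect_equal(net1$edges$upDist_m, net1$edges$length_m)

  tv <- tv_pipeline(n_valleys = 2)
  expect_equal(nrow(tv$net$edges), 3)
  expect_setequal(tv$net$edges$binaryID, c("1", "10", "11"))
  out <- tv$net$edges[tv$net$edges$binaryID == "1", ]
  expect_equal(out$shreve, 2L)
  # upDist recursion: upstream edge upDist = outlet upDist + its length
  for (b in c("10", "11")) {
    e <- tv$net$edges[tv$net$edges$binaryID == b, ]
    expect_equal(e$upDist_m, out$upDist_m + e$length_m)
  }
  # direction follows decreasing elevation
  for (r in tv$net$edges$rid) {
    g <- tv$net$geoms[[as.character(r)]]
    zz <- tv$demf$values[xy_cell(tv$demf, g[, 1], g[, 2])]
    expect_true(all(diff(zz) < 1e-9))
  }

  basins <- carved_net(two_basin_dem())
  expect_setequal(basins$edges$netID, c(1L, 2L))
  expect_equal(sort(basins$edges$binaryID), c("1", "1"))
  # netID 1 is the south-most/west-most outlet: both outlets at the same y,
  # so the west one comes first
  o <- basins$edges[order(basins$edges$netID), ]
  g1 <- basins$geoms[[as.character(o$rid[1])]]
  g2 <- basins$geoms[[as.character(o$rid[2])]]
  expect_lt(g1[nrow(g1), 1], g2[nrow(g2), 1])
})

test_that("complex confluence detection and correction (3- and 4-inflow)", {
  tv3 <- tv_pipeline(n_valleys = 3)
  bad <- check_complex_confluences(tv3$net)
  expect_length(bad, 1)
  before_h2o <- outlet_edges(tv3$net)$h2o_km2
  fixed <- correct_complex_confluences(tv3$net)
  expect_length(check_complex_confluences(fixed), 0)
  expect_equal(sum(fixed$edges$artificial), 1L)          # 3 inflows -> 1 stub
  expect_equal(nrow(fixed$edges), nrow(tv3$net$edges) + 1L)
  expect_equal(sum(fixed$nodes$kind == "pseudo"), 1L)
  expect_equal(outlet_edges(fixed)$h2o_km2, before_h2o)  # area conserved
  expect_true(admissibility_census(fixed)$admissible)
  # the stub is offset_fraction * cell_size long
  stub <- fixed$edges[fixed$edges$artificial, ]
  expect_equal(stub$length_m, 0.25 * fixed$grid$cell_size, tolerance = 1e-9)

  net4 <- carved_net(four_inflow_dem())
  n4 <- check_complex_confluences(net4)
  expect_length(n4, 1)
  expect_equal(sum(net4$edges$to_node == n4), 4L)
  fixed4 <- correct_complex_confluences(net4)
  expect_equal(sum(fixed4$edges$artificial), 2L)         # 4 inflows -> 2 stubs
  expect_length(check_complex_confluences(fixed4), 0)
  expect_true(admissibility_census(fixed4)$admissible)
  expect_area_additive(fixed4)
  expect_error(correct_complex_confluences(net4, 0.7), "offset_fraction")
})

test_that("binaryID encoding: root, child extension, uniqueness, prefix property", {
  nets <- list(correct_complex_confluences(tv_pipeline(n_valleys = 3)$net),
               correct_complex_confluences(carved_net(four_inflow_dem())),
               tv_pipeline(n_valleys = 2)$net)
  for (net in nets) {
    e <- net$edges
    for (nid in unique(e$netID)) {
      sub <- e[e$netID == nid, ]
      expect_equal(sum(sub$binaryID == "1"), 1L)
      expect_false(anyDuplicated(sub$binaryID) > 0)
    }
    prev <- streamprep:::prev_rids_for(e)
    for (i in seq_len(nrow(e))) {
      for (p in prev[[i]]) {
        pb <- e$binaryID[match(p, e$rid)]
        expect_equal(nchar(pb), nchar(e$binaryID[i]) + 1L)
        expect_equal(substr(pb, 1, nchar(e$binaryID[i])), e$binaryID[i])
      }
    }
    # full prefix property on all upstream pairs
    for (i in seq_len(nrow(e))) {
      up <- streamprep:::prev_rids_for(e)[[i]]
      while (length(up)) {
        bi <- e$binaryID[match(up, e$rid)]
        expect_true(all(startsWith(bi, e$binaryID[i])))
        up <- unlist(lapply(match(up, e$rid), function(j) prev[[j]]))
      }
    }
  }
})

test_that("area additivity holds before/after correction and lake deletion", {
  tv3 <- tv_pipeline(n_valleys = 3)
  expect_area_additive(tv3$net)
  fixed <- correct_complex_confluences(tv3$net)
  expect_area_additive(fixed)
  # lake over the trunk: severs the upstream subtree
  trunk_rid <- fixed$edges$rid[fixed$edges$binaryID == "1"]
  g <- fixed$geoms[[as.character(trunk_rid)]]
  mid <- g[ceiling(nrow(g) / 2), ]
  lake <- cbind(mid[1] + c(-15, 15, 15, -15), mid[2] + c(-15, -15, 15, 15))
  n_nets_before <- length(unique(fixed$edges$netID))
  cut <- delete_lakes(fixed, list(lake))
  expect_equal(length(unique(cut$edges$netID)), n_nets_before + 1L)
  expect_false(trunk_rid %in% cut$edges$rid)       # rid retired
  expect_area_additive(cut)
  for (nid in unique(cut$edges$netID)) {
    sub <- cut$edges[cut$edges$netID == nid, ]
    expect_equal(sum(sub$binaryID == "1"), 1L)     # fresh root per network
  }
  expect_true(admissibility_census(cut)$admissible)
})

test_that("delete_lakes identities and severed-subtree counting", {
  tv <- tv_pipeline(n_valleys = 2)
  expect_identical(delete_lakes(tv$net, list()), tv$net)
  far_lake <- cbind(c(-100, -90, -90, -100), c(-100, -100, -90, -90))
  expect_identical(delete_lakes(tv$net, list(far_lake)), tv$net)

  # lake over the Y's outlet edge: the two tributaries become one network
  # each (each severed in-tree is its own network, so each keeps exactly one
  # outflow)
  out_rid <- tv$net$edges$rid[tv$net$edges$binaryID == "1"]
  g <- tv$net$geoms[[as.character(out_rid)]]
  ctr <- g[ceiling(nrow(g) / 2), ]
  lake <- cbind(ctr[1] + c(-5, 5, 5, -5), ctr[2] + c(-5, -5, 5, 5))
  cut <- delete_lakes(tv$net, list(lake))
  expect_equal(nrow(cut$edges), 2)
  expect_equal(length(unique(cut$edges$netID)), 2)
  expect_equal(as.integer(table(cut$edges$netID)), c(1L, 1L))
  expect_equal(cut$edges$binaryID, c("1", "1"))
  expect_true(admissibility_census(cut)$admissible)
  expect_area_additive(cut)

  # netID bookkeeping: kept networks retain their id, severed roots get
  # fresh ones equal in number to the new outlet edges
  net <- carved_net(spur_dem())     # 5 edges, two junctions
  mid_rid <- net$edges$rid[net$edges$shreve == 2][1]
  gm <- net$geoms[[as.character(mid_rid)]]
  ctr <- gm[ceiling(nrow(gm) / 2), ]
  lake2 <- cbind(ctr[1] + c(-5, 5, 5, -5), ctr[2] + c(-5, -5, 5, 5))
  cut2 <- delete_lakes(net, list(lake2))
  removed <- setdiff(net$edges$rid, cut2$edges$rid)
  severed_roots <- sum(!(cut2$edges$to_node %in% cut2$edges$from_node)) - 1L
  expect_equal(length(unique(cut2$edges$netID)), 1L + severed_roots)
  expect_true(all(removed == mid_rid))
  expect_true(admissibility_census(cut2)$admissible)
})
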