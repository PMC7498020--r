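# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Full derivation for a twin-valley fixture: list(spec, dem, demf, fd, acc, net).
tv_pipeline <- function(n_valleys = 2, seed = 42, threshold = 20, msl = 15,
                        routing = "mfd", nrows = 60, ncols = 60) {
  key <- paste("tv", n_valleys, seed, threshold, msl, routing, nrows, ncols, sep = "_")
  cached(key, function() {
    spec <- fixture_spec(nrows = nrows, ncols = ncols, relief = "twin_valley",
                         n_valleys = n_valleys, seed = seed)
    dem <- make_dem(spec)
    demf <- fill_depressions(dem)
    fd <- if (routing == "mfd") mfd_directions(demf) else d8_directions(demf)
    acc <- accumulate(fd, routing)
    net <- vectorize(extract_streams(acc, fd, threshold, msl), fd, demf)
    list(spec = spec, dem = dem, demf = demf, fd = fd, acc = acc, net = net)
  })
}

# DEM with explicitly carved channels on a nodata background: only the
# channel cells carry elevations, strictly decreasing toward each outlet, so
# D8 follows the carved paths exactly and accumulation equals the carved
# chain counts. `channel_cells` is a list of (row, col) matrices;
# `channel_z` the matching elevation vectors.
carve_dem <- function(nr, nc, channel_cells, channel_z, cell_size = 10) {
  z <- matrix(NA_real_, nr, nc)
  for (i in seq_along(channel_cells)) {
    rc <- channel_cells[[i]]
    z[cbind(rc[, 1], rc[, 2])] <- channel_z[[i]]
  }
  raster_grid(z, cell_size = cell_size)
}

# Four channels (W, NW, N, NE) converging on one junction cell, the trunk
# continuing due south to the boundary: a guaranteed 4-inflow node.
four_inflow_dem <- function(nr = 31, nc = 31) {
  jr <- 16L; jc <- 16L
  trunk <- cbind(jr:nr, jc)
  # gentle trunk descent: steeper would let the W inflow shortcut diagonally
  # into the trunk cell below the junction instead of entering the junction
  trunk_z <- seq(50, by = -0.25, length.out = nrow(trunk))
  west <- cbind(jr, (jc - 1):2)
  north <- cbind((jr - 1):2, jc)
  nw <- cbind((jr - 1):2, (jc - 1):2)
  ne <- cbind((jr - 1):2, (jc + 1):(nc - 1))
  carve_dem(nr, nc, list(trunk, west, north, nw, ne),
            list(trunk_z, 50 + seq_len(nrow(west)), 50 + seq_len(nrow(north)),
                 50 + 1.5 * seq_len(nrow(nw)), 50 + 1.5 * seq_len(nrow(ne))))
}

# Straight main channel with two headwater spurs of given cell counts.
spur_dem <- function(nr = 20, nc = 20, spur1 = 3, spur2 = 5) {
  mc <- 10L
  main <- cbind(2:nr, mc)
  main_z <- 50 + (nr - (2:nr))
  j1 <- 6L; j2 <- 12L
  s1 <- cbind(j1, (mc - 1):(mc - spur1))
  s1_z <- main_z[match(j1, main[, 1])] + seq_len(spur1)
  s2 <- cbind(j2, (mc + 1):(mc + spur2))
  s2_z <- main_z[match(j2, main[, 1])] + seq_len(spur2)
  carve_dem(nr, nc, list(main, s1, s2), list(main_z, s1_z, s2_z))
}

# Two parallel carved channels that never meet: two disjoint basins.
two_basin_dem <- function(nr = 15, nc = 15) {
  c1 <- cbind(2:nr, 4L); c2 <- cbind(2:nr, 11L)
  z <- 50 + (nr - (2:nr))
  carve_dem(nr, nc, list(c1, c2), list(z, z))
}

# Small random smooth DEM (seeded) for property tests.
random_dem <- function(seed, nr = 20, nc = 20, noise_sd = 3) {
  fill_depressions(make_dem(fixture_spec(nrows = nr, ncols = nc,
                                         relief = "random_smooth",
                                         noise_sd = noise_sd, seed = seed)))
}

# Derive a network from a carved DEM (threshold 1: every channel cell is a
# stream cell).
carved_net <- function(dem, threshold = 1, msl = 0) {
  fd <- d8_directions(dem)
  vectorize(extract_streams(accumulate(fd, "d8"), fd, threshold, msl), fd, dem)
}

expect_area_additive <- function(net, tol = 1e-12) {
  for (nid in unique(net$edges$netID)) {
    sub <- net$edges[net$edges$netID == nid, ]
    outlet <- sub[!(sub$to_node %in% sub$from_node), ]
    expect_equal(sum(sub$rca_km2), outlet$h2o_km2, tolerance = tol)
  }
}
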