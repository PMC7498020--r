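# Deterministic synthetic inputs: drainable terrain, jittered sites, and a
# categorical land-use layer in exactly consistent raster and polygon form.
# Everything is driven by one seeded specification, so identical specs give
# bit-identical fixtures.

#' Synthetic fixture specification
#'
#' @param nrows,ncols grid dimensions (>= 5).
#' @param cell_size cell edge in metres.
#' @param relief terrain family: `"tilted_plane"` (strictly monotone,
#'   single-outlet, confluence-free), `"twin_valley"` (`n_valleys` parabolic
#'   valleys converging on one junction and draining south through a common
#'   trunk: >= 1 confluence, and with `n_valleys >= 3` a complex confluence
#'   at coarse extraction thresholds) or `"random_smooth"` (low-pass-filtered
#'   noise plus a tilt).
#' @param noise_sd standard deviation (m) of smoothed Gaussian noise added to
#'   the surface.
#' @param n_sites number of synthetic observation sites.
#' @param site_jitter_m per-coordinate Gaussian jitter applied to sites (m).
#' @param n_classes number of land-use classes (>= 1).
#' @param n_valleys number of valleys for the `twin_valley` relief.
#' @param seed integer PRNG seed; same spec + seed => identical outputs.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(nrows = 60, ncols = 60, cell_size = 10,
                         relief = c("twin_valley", "tilted_plane", "random_smooth"),
                         noise_sd = 0, n_sites = 20, site_jitter_m = 5,
                         n_classes = 3, n_valleys = 2, seed = 42) {
  relief <- match.arg(relief)
  if (nrows < 5 || ncols < 5) stop("fixture grids must be at least 5 x 5")
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 cell_size = cell_size, relief = relief, noise_sd = noise_sd,
                 n_sites = as.integer(n_sites), site_jitter_m = site_jitter_m,
                 n_classes = as.integer(n_classes), n_valleys = as.integer(n_valleys),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic DEM
#'
#' @param spec a [fixture_spec()].
#' @return A [raster_grid()] of elevations in metres.
#' @export
make_dem <- function(spec) {
  nr <- spec$nrows; nc <- spec$ncols; cs <- spec$cell_size
  r <- matrix(rep(seq_len(nr), nc), nr, nc)
  c_ <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  z <- switch(spec$relief,
    tilted_plane = {
      # tilted equally in x and y; single outlet at the SE corner
      1.0 * ((nr - r) + (nc - c_)) + 50
    },
    twin_valley = twin_valley_surface(nr, nc, spec$n_valleys),
    random_smooth = {
      withr_seed(spec$seed, {
        noise <- matrix(stats::rnorm(nr * nc), nr, nc)
        for (i in 1:6) noise <- smooth3(noise)
        noise <- noise / stats::sd(noise) * max(spec$noise_sd, 2)
        noise + 0.6 * (nr - r) + 0.25 * (nc - c_) + 50
      })
    })
  if (spec$noise_sd > 0 && spec$relief != "random_smooth") {
    z <- z + withr_seed(spec$seed + 1L, {
      n2 <- matrix(stats::rnorm(nr * nc), nr, nc)
      for (i in 1:3) n2 <- smooth3(n2)
      n2 / stats::sd(n2) * spec$noise_sd
    })
  }
  raster_grid(z, cell_size = cs, origin_x = 0, origin_y = nr * cs,
              nodata = -9999, crs_tag = "LOCAL_CARTESIAN")
}

# Valley-and-trunk surface: elevation = a * (along-channel distance to the
# outlet) + b * (perpendicular distance to the nearest channel)^2, over
# n_valleys straight channels from the north boundary converging on one
# junction, plus a trunk from the junction straight south to the outlet.
# Coefficients sized so accum_threshold ~ 20 on a 60x60 grid yields a small
# single-digit edge count.
twin_valley_surface <- function(nr, nc, n_valleys) {
  rj <- floor(0.65 * nr); cj <- floor((nc + 1) / 2)
  tips_c <- round(seq(0.15, 0.85, length.out = n_valleys) * nc)
  j <- c(rj, cj); outlet <- c(nr, cj)
  a <- 1.0; b <- 1.6   # cross-valley gradient >> down-valley, so D8 converges onto the channel lines
  trunk_len <- nr - rj
  z <- matrix(0, nr, nc)
  for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
    p <- c(rr, cc)
    best <- Inf
    # trunk: vertical segment junction -> outlet
    tseg <- nearest_on_segment(p[2], p[1], j[2], j[1], outlet[2], outlet[1])
    d_perp <- sqrt((p[2] - tseg[1])^2 + (p[1] - tseg[2])^2)
    along <- outlet[1] - tseg[2]               # rows to outlet along trunk
    best <- a * along + b * d_perp^2
    for (tc in tips_c) {
      vseg <- nearest_on_segment(p[2], p[1], tc, 1, j[2], j[1])
      d_perp <- sqrt((p[2] - vseg[1])^2 + (p[1] - vseg[2])^2)
      along <- sqrt((vseg[1] - j[2])^2 + (vseg[2] - j[1])^2) + trunk_len
      best <- min(best, a * along + b * d_perp^2)
    }
    z[rr, cc] <- best
  }
  z + 20
}

smooth3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[1, ], m[-nr, ]); dn <- rbind(m[-1, ], m[nr, ])
  lf <- cbind(m[, 1], m[, -nc]); rt <- cbind(m[, -1], m[, nc])
  (m + up + dn + lf + rt) / 5
}

# Run code under a local RNG seed without disturbing the caller's RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate synthetic observation sites along a network
#'
#' Samples positions uniformly along the network's edges (length-weighted),
#' records the true `(rid, ratio)` of every position, then jitters the
#' coordinates with independent Gaussian noise — so snapping can be tested
#' against a known truth.
#'
#' @param spec a [fixture_spec()] (`n_sites`, `site_jitter_m`, `seed`).
#' @param net a `stream_network`.
#' @return data.frame with columns `site_id, x, y, true_rid, true_ratio`.
#' @export
make_sites <- function(spec, net) {
  e <- net$edges[!net$edges$artificial, , drop = FALSE]
  if (!nrow(e)) stop("network has no non-artificial edges")
  withr_seed(spec$seed + 2L, {
    w <- e$length_m / sum(e$length_m)
    pick <- sample.int(nrow(e), spec$n_sites, replace = TRUE, prob = w)
    t <- stats::runif(spec$n_sites)
    out <- data.frame(site_id = seq_len(spec$n_sites), x = NA_real_, y = NA_real_,
                      true_rid = e$rid[pick], true_ratio = NA_real_)
    for (i in seq_len(spec$n_sites)) {
      g <- net$geoms[[as.character(e$rid[pick[i]])]]
      L <- e$length_m[pick[i]]
      s <- t[i] * L                      # arc length from the upstream end
      p <- polyline_point_at(g, s)
      out$x[i] <- p[1]; out$y[i] <- p[2]
      out$true_ratio[i] <- (L - s) / L   # measured from the downstream node
    }
    out$x <- out$x + stats::rnorm(spec$n_sites, 0, spec$site_jitter_m)
    out$y <- out$y + stats::rnorm(spec$n_sites, 0, spec$site_jitter_m)
    out
  })
}

#' Generate a categorical land-use layer (raster + matching polygons)
#'
#' A seeded mosaic of axis-aligned rectangular patches covering the grid,
#' each assigned one of `n_classes` classes (every class occurs at least
#' once when there are enough patches). The polygon layer and the raster are
#' cell-for-cell consistent by construction — the raster is produced by
#' cell-centre-in-polygon rasterisation of the very same rectangles — so the
#' raster and vector predictor paths can be cross-checked exactly.
#'
#' @param spec a [fixture_spec()] (`n_classes`, `seed`).
#' @param dem template [raster_grid()].
#' @return list with `raster` (categorical [raster_grid()]), `polygons`
#'   (list of rectangle rings) and `classes` (integer class per polygon).
#' @export
make_landuse <- function(spec, dem) {
  if (spec$n_classes < 1) stop("n_classes must be >= 1")
  nrect <- max(3L * spec$n_classes, 8L)
  xmin <- dem$origin_x; xmax <- dem$origin_x + dem$ncols * dem$cell_size
  ymin <- dem$origin_y - dem$nrows * dem$cell_size; ymax <- dem$origin_y
  withr_seed(spec$seed + 3L, {
    rects <- list(c(xmin, xmax, ymin, ymax))
    while (length(rects) < nrect) {
      areas <- vapply(rects, function(r) (r[2] - r[1]) * (r[4] - r[3]), numeric(1))
      i <- which.max(areas)
      r <- rects[[i]]
      f <- stats::runif(1, 0.3, 0.7)
      if ((r[2] - r[1]) >= (r[4] - r[3])) {   # split the longer axis
        xm <- r[1] + f * (r[2] - r[1])
        new <- list(c(r[1], xm, r[3], r[4]), c(xm, r[2], r[3], r[4]))
      } else {
        ym <- r[3] + f * (r[4] - r[3])
        new <- list(c(r[1], r[2], r[3], ym), c(r[1], r[2], ym, r[4]))
      }
      rects <- c(rects[-i], new)
    }
    classes <- c(seq_len(spec$n_classes),
                 sample.int(spec$n_classes, length(rects) - spec$n_classes, replace = TRUE))
    classes <- classes[seq_along(rects)]
    rings <- lapply(rects, function(r)
      cbind(c(r[1], r[2], r[2], r[1]), c(r[3], r[3], r[4], r[4])))
    rast <- rasterize_polygons(dem, rings, classes)
    list(raster = rast, polygons = rings, classes = classes)
  })
}
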