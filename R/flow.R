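# Flow routing on a depression-filled DEM: D8 and Freeman-style MFD
# directions, flow accumulation, and upstream-cell (catchment) tracing.
#
# Neighbour order is fixed as E, SE, S, SW, W, NW, N, NE throughout; ties in
# the steepest-descent choice are broken by the lowest neighbour index in
# this order, which makes every result deterministic.

#' D8 flow directions
#'
#' Each cell drains to the neighbour with the steepest descent, with drop
#' divided by distance (`cell_size` for cardinal, `cell_size * sqrt(2)` for
#' diagonal neighbours). Cells with no strictly lower neighbour are outlets
#' (coded -1) when they can drain off-grid (on the boundary or next to a
#' nodata cell); an interior cell with no descent is an error — fill the DEM
#' first with [fill_depressions()].
#'
#' @param dem a depression-filled [raster_grid()].
#' @return A `flow_dir` object holding the D8 code matrix (1-8 = neighbour
#'   index, -1 = outlet, NA = nodata), a downstream-cell index matrix, and
#'   the elevations used (for topological ordering).
#' @export
d8_directions <- function(dem) {
  stopifnot(inherits(dem, "raster_grid"))
  z <- dem$values
  nr <- dem$nrows; nc <- dem$ncols
  offs <- nbr_offsets()
  dist <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)) * dem$cell_size  # E,SE,S,SW,W,NW,N,NE
  best_slope <- matrix(-Inf, nr, nc)
  best_dir <- matrix(NA_integer_, nr, nc)
  can_exit <- matrix(FALSE, nr, nc)
  can_exit[1, ] <- TRUE; can_exit[nr, ] <- TRUE; can_exit[, 1] <- TRUE; can_exit[, nc] <- TRUE
  na_m <- is.na(z)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    zn <- shift_matrix_num(z, o[1], o[2])          # neighbour elevation (NA off-grid)
    off_or_nodata <- is.na(zn)
    can_exit <- can_exit | off_or_nodata
    slope <- (z - zn) / dist[k]
    upd <- !is.na(slope) & slope > 0 & slope > best_slope + 0  # strict improvement only
    best_dir[upd] <- k
    best_slope[upd] <- slope[upd]
  }
  no_desc <- is.na(best_dir) & !na_m
  if (any(no_desc & !can_exit))
    stop("interior cell(s) with no downslope neighbour: depression-fill the DEM first")
  d8 <- best_dir
  d8[no_desc] <- -1L
  d8[na_m] <- NA_integer_
  structure(list(d8 = d8, target = d8_targets(d8, nr, nc),
                 mfd = NULL, elev = z,
                 nrows = nr, ncols = nc, cell_size = dem$cell_size,
                 origin_x = dem$origin_x, origin_y = dem$origin_y,
                 crs_tag = dem$crs_tag),
            class = "flow_dir")
}

# Downstream cell index per cell (NA at outlets/nodata).
d8_targets <- function(d8, nr, nc) {
  offs <- nbr_offsets()
  tgt <- matrix(NA_integer_, nr, nc)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    sel <- which(!is.na(d8) & d8 == k)
    if (!length(sel)) next
    col <- (sel - 1L) %/% nr + 1L; row <- sel - (col - 1L) * nr
    tgt[sel] <- (col + o[2] - 1L) * nr + (row + o[1])
  }
  tgt
}

shift_matrix_num <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 > r2 || c1 > c2) return(out)
  rs <- r1:r2; cs <- c1:c2
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Multiple-flow-direction (MFD) weights
#'
#' Freeman-scheme partitioning: outflow to each strictly lower neighbour is
#' proportional to `slope^exponent`, normalised so that the weights of every
#' draining cell sum to 1. The D8 code matrix is computed alongside (used
#' for crisp catchment delineation).
#'
#' @param dem a depression-filled [raster_grid()].
#' @param exponent slope exponent; 1.1 is the customary Freeman value.
#' @return A `flow_dir` object whose `mfd` field is an `nrows x ncols x 8`
#'   weight array.
#' @export
mfd_directions <- function(dem, exponent = 1.1) {
  fd <- d8_directions(dem)
  z <- dem$values
  nr <- dem$nrows; nc <- dem$ncols
  dist <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)) * dem$cell_size
  w <- array(0, dim = c(nr, nc, 8L))
  offs <- nbr_offsets()
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    zn <- shift_matrix_num(z, o[1], o[2])
    slope <- (z - zn) / dist[k]
    pos <- !is.na(slope) & slope > 0
    wk <- matrix(0, nr, nc)
    wk[pos] <- slope[pos]^exponent
    w[, , k] <- wk
  }
  tot <- apply(w, c(1, 2), sum)
  drain <- tot > 0
  for (k in 1:8) {
    wk <- w[, , k]
    wk[drain] <- wk[drain] / tot[drain]
    wk[!drain] <- 0
    w[, , k] <- wk
  }
  fd$mfd <- w
  fd
}

#' Flow accumulation
#'
#' Per-cell accumulated area in cells, including the cell itself. Cells are
#' processed in decreasing elevation order, which is a valid topological
#' order because flow always descends strictly on a filled DEM. Under D8 the
#' whole cell passes downstream; under MFD the Freeman weights split it.
#'
#' @param fd a `flow_dir` from [d8_directions()] or [mfd_directions()].
#' @param mode `"d8"` or `"mfd"` (the latter requires MFD weights).
#' @return A [raster_grid()] of accumulation values (>= 1 everywhere).
#' @export
accumulate <- function(fd, mode = c("d8", "mfd")) {
  mode <- match.arg(mode)
  if (mode == "mfd" && is.null(fd$mfd))
    stop("flow_dir has no MFD weights; use mfd_directions()")
  nr <- fd$nrows; nc <- fd$ncols
  acc <- matrix(1, nr, nc)
  acc[is.na(fd$d8)] <- NA_real_
  live <- which(!is.na(fd$d8))
  ord <- live[order(fd$elev[live], decreasing = TRUE)]
  offs <- nbr_offsets()
  if (mode == "d8") {
    tgt <- fd$target
    for (i in ord) {
      t <- tgt[i]
      if (!is.na(t)) acc[t] <- acc[t] + acc[i]
    }
  } else {
    ncell <- nr * nc
    # flattened neighbour index offset per direction k
    doff <- vapply(offs, function(o) o[1] + o[2] * nr, numeric(1))
    w <- fd$mfd
    for (i in ord) {
      col <- (i - 1L) %/% nr + 1L; row <- i - (col - 1L) * nr
      for (k in 1:8) {
        wk <- w[row, col, k]
        if (wk > 0) {
          j <- i + doff[k]
          acc[j] <- acc[j] + wk * acc[i]
        }
      }
    }
  }
  raster_grid(acc, cell_size = fd$cell_size, origin_x = fd$origin_x,
              origin_y = fd$origin_y, nodata = -9999, crs_tag = fd$crs_tag)
}

#' Upstream cells of a seed cell (exact catchment)
#'
#' All cells whose D8 flow path passes through `seed`, including the seed
#' itself — the exact catchment of the seed cell, as a set of cell indices.
#'
#' @param fd a `flow_dir`.
#' @param seed a single cell index (column-major).
#' @return Integer vector of cell indices (sorted).
#' @export
upstream_cells <- function(fd, seed) {
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed) || seed < 1L || seed > fd$nrows * fd$ncols)
    stop("seed must be a single on-grid cell index")
  if (is.na(fd$d8[seed])) stop("seed cell is nodata")
  donors <- donor_lists(fd)
  out <- integer(0)
  queue <- seed
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(donors[queue], use.names = FALSE)
  }
  sort(out)
}

# List of inflowing (donor) cells per cell, from the D8 target matrix.
donor_lists <- function(fd) {
  if (!is.null(fd$.donors)) return(fd$.donors)
  n <- fd$nrows * fd$ncols
  tgt <- fd$target
  have <- which(!is.na(tgt))
  d <- vector("list", n)
  if (length(have)) {
    sp <- split(have, tgt[have])
    d[as.integer(names(sp))] <- sp
  }
  d
}
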