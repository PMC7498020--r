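# DEM conditioning: stream burning and depression filling.

#' Rasterize polylines onto a grid (all-touched)
#'
#' A cell is marked when any polyline segment passes through its square
#' (supercover traversal), which guarantees an 8-connected — in fact
#' 4-connected — chain of burned cells along the line, and hence a
#' hydrologically connected channel after burning.
#'
#' @param grid template [raster_grid()].
#' @param lines list of polylines (2-column xy matrices).
#' @return integer vector of cell indices touched by any line.
#' @export
rasterize_lines <- function(grid, lines) {
  cs <- grid$cell_size
  hits <- integer(0)
  for (pts in lines) {
    if (is.null(pts) || nrow(pts) < 2L) next
    for (i in seq_len(nrow(pts) - 1L)) {
      hits <- c(hits, trace_segment_cells(grid, pts[i, 1], pts[i, 2], pts[i + 1L, 1], pts[i + 1L, 2]))
    }
  }
  sort(unique(hits))
}

# Amanatides-Woo style traversal of all cells crossed by one segment.
trace_segment_cells <- function(grid, ax, ay, bx, by) {
  cs <- grid$cell_size
  # grid-local coordinates: u right in columns, v down in rows
  ux <- (ax - grid$origin_x) / cs; vy <- (grid$origin_y - ay) / cs
  wx <- (bx - grid$origin_x) / cs; zy <- (grid$origin_y - by) / cs
  col <- floor(ux); row <- floor(vy)
  col_end <- floor(wx); row_end <- floor(zy)
  dx <- wx - ux; dy <- zy - vy
  step_c <- sign(dx); step_r <- sign(dy)
  t_max_c <- if (dx != 0) ((col + (dx > 0)) - ux) / dx else Inf
  t_max_r <- if (dy != 0) ((row + (dy > 0)) - vy) / dy else Inf
  t_delta_c <- if (dx != 0) abs(1 / dx) else Inf
  t_delta_r <- if (dy != 0) abs(1 / dy) else Inf
  cells <- integer(0)
  record <- function(r, c) {
    if (r >= 0 && r < grid$nrows && c >= 0 && c < grid$ncols)
      cells[[length(cells) + 1L]] <<- cell_index(grid, as.integer(r) + 1L, as.integer(c) + 1L)
  }
  max_steps <- abs(col_end - col) + abs(row_end - row) + 2L
  for (k in seq_len(max_steps + 1L)) {
    record(row, col)
    if (col == col_end && row == row_end) break
    if (abs(t_max_c - t_max_r) < 1e-12 && is.finite(t_max_c)) {
      # exact corner crossing: the two side cells are touched too
      record(row + step_r, col)
      record(row, col + step_c)
      col <- col + step_c; row <- row + step_r
      t_max_c <- t_max_c + t_delta_c; t_max_r <- t_max_r + t_delta_r
    } else if (t_max_c < t_max_r) {
      col <- col + step_c; t_max_c <- t_max_c + t_delta_c
    } else {
      row <- row + step_r; t_max_r <- t_max_r + t_delta_r
    }
  }
  cells <- unlist(cells)
  if (is.null(cells)) integer(0) else cells
}

#' Burn a stream network into a DEM
#'
#' Lowers the elevation of every cell crossed by a mapped channel by
#' `burn_depth` metres, guiding the DEM-derived streams onto the mapped
#' network. Cells are selected all-touched (see [rasterize_lines()]); each
#' selected cell is lowered exactly once regardless of how many lines cross
#' it.
#'
#' @param dem a [raster_grid()] of elevations (m).
#' @param streams list of polylines (2-column xy matrices), or the result of
#'   [read_geojson()] on a line layer.
#' @param burn_depth metres to lower burned cells, `>= 0`.
#' @return A new [raster_grid()]; the input is not modified.
#' @export
burn_streams <- function(dem, streams, burn_depth) {
  stopifnot(inherits(dem, "raster_grid"))
  if (!is.numeric(burn_depth) || length(burn_depth) != 1L || !is.finite(burn_depth) || burn_depth < 0)
    stop("burn_depth must be a single finite number >= 0")
  if (is.list(streams) && !is.null(streams$geoms)) streams <- streams$geoms
  if (length(streams) == 0L) {
    warning("empty stream set: DEM returned unchanged")
    return(dem)
  }
  cells <- rasterize_lines(dem, streams)
  out <- dem
  out$values[cells] <- out$values[cells] - burn_depth
  out
}

# ---- binary min-heap on (key, value) pairs ------------------------------

heap_new <- function(capacity = 1024L) {
  e <- new.env(parent = emptyenv())
  e$key <- numeric(capacity); e$val <- integer(capacity); e$n <- 0L
  e
}

heap_push <- function(h, key, val) {
  n <- h$n + 1L
  if (n > length(h$key)) {
    h$key <- c(h$key, numeric(length(h$key)))
    h$val <- c(h$val, integer(length(h$val)))
  }
  h$key[n] <- key; h$val[n] <- val; h$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (h$key[p] <= h$key[i]) break
    tk <- h$key[p]; h$key[p] <- h$key[i]; h$key[i] <- tk
    tv <- h$val[p]; h$val[p] <- h$val[i]; h$val[i] <- tv
    i <- p
  }
  invisible(h)
}

heap_pop <- function(h) {
  if (h$n == 0L) stop("pop from empty heap")
  top <- c(h$key[1L], h$val[1L])
  h$key[1L] <- h$key[h$n]; h$val[1L] <- h$val[h$n]; h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; s <- i
    if (l <= h$n && h$key[l] < h$key[s]) s <- l
    if (r <= h$n && h$key[r] < h$key[s]) s <- r
    if (s == i) break
    tk <- h$key[s]; h$key[s] <- h$key[i]; h$key[i] <- tk
    tv <- h$val[s]; h$val[s] <- h$val[i]; h$val[i] <- tv
    i <- s
  }
  top
}

#' Fill depressions in a DEM (priority-flood with epsilon gradient)
#'
#' Raises every interior pit just enough that all non-nodata cells have a
#' strictly descending 8-neighbour path to the grid boundary (or to a nodata
#' cell, which is treated as off-grid). No cell is ever lowered. The small
#' epsilon increment (`eps`, default 1e-5 m per step) resolves flats so that
#' downstream flow directions are well defined everywhere.
#'
#' @param dem a [raster_grid()].
#' @param eps epsilon gradient in metres per cell step.
#' @return A filled [raster_grid()]; idempotent (`fill(fill(x)) == fill(x)`).
#' @export
fill_depressions <- function(dem, eps = 1e-5) {
  stopifnot(inherits(dem, "raster_grid"))
  z <- dem$values
  nr <- dem$nrows; nc <- dem$ncols
  if (all(is.na(z))) stop("all-nodata grid cannot be filled")
  n <- nr * nc
  visited <- is.na(z)  # nodata never enters the queue
  out <- z
  h <- heap_new(max(1024L, 2L * (nr + nc)))
  # seed: boundary cells and cells adjacent to nodata
  is_seed <- matrix(FALSE, nr, nc)
  is_seed[1, ] <- TRUE; is_seed[nr, ] <- TRUE; is_seed[, 1] <- TRUE; is_seed[, nc] <- TRUE
  if (any(is.na(z))) {
    na_m <- is.na(z)
    for (off in nbr_offsets()) {
      shifted <- shift_matrix_logical(na_m, off[1], off[2])
      is_seed <- is_seed | shifted
    }
  }
  seeds <- which(is_seed & !is.na(z))
  for (s in seeds) {
    heap_push(h, z[s], s)
    visited[s] <- TRUE
  }
  if (h$n == 0L) stop("no non-nodata cell on the grid boundary; cannot fill")
  offs <- nbr_offsets()
  while (h$n > 0L) {
    top <- heap_pop(h)
    zc <- top[1]; idx <- as.integer(top[2])
    col <- (idx - 1L) %/% nr + 1L; row <- idx - (col - 1L) * nr
    for (o in offs) {
      rr <- row + o[1]; cc <- col + o[2]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      j <- (cc - 1L) * nr + rr
      if (visited[j]) next
      visited[j] <- TRUE
      nz <- max(out[j], zc + eps)
      out[j] <- nz
      heap_push(h, nz, j)
    }
  }
  res <- dem
  res$values <- out
  res
}

# D8 neighbour offsets in the canonical order E, SE, S, SW, W, NW, N, NE
# (row 1 is north, so S is +row).
nbr_offsets <- function() {
  list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L),
       c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L))
}

# Shift a logical matrix by (dr, dc), padding with FALSE: result[r,c] =
# m[r+dr, c+dc] clipped at edges.
shift_matrix_logical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 > r2 || c1 > c2) return(out)
  rs <- r1:r2; cs <- c1:c2
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}
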