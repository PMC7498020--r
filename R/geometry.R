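# Small planar-geometry toolkit (no external GIS dependency).
# Polylines are 2-column xy matrices; polygons are 2-column xy matrices with
# an implicitly closed ring; multi-part features are lists of such matrices.

polyline_length <- function(pts) {
  if (is.null(pts) || nrow(pts) < 2L) return(0)
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

# Cumulative arc length at each vertex (first = 0).
polyline_cumlen <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
}

# Point on a polyline at arc length s from its first vertex (clamped).
polyline_point_at <- function(pts, s) {
  cl <- polyline_cumlen(pts)
  L <- cl[length(cl)]
  s <- min(max(s, 0), L)
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  seg <- cl[i + 1L] - cl[i]
  t <- if (seg > 0) (s - cl[i]) / seg else 0
  c(pts[i, 1] + t * (pts[i + 1L, 1] - pts[i, 1]),
    pts[i, 2] + t * (pts[i + 1L, 2] - pts[i, 2]))
}

# Truncate a polyline to arc length [0, s]; last vertex interpolated at s.
polyline_clip_head <- function(pts, s) {
  cl <- polyline_cumlen(pts)
  L <- cl[length(cl)]
  if (s >= L) return(pts)
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  p <- polyline_point_at(pts, s)
  out <- rbind(pts[seq_len(i), , drop = FALSE], p)
  # drop duplicated vertex if s fell exactly on one
  if (i >= 1L && all(abs(out[nrow(out) - 1L, ] - p) < 1e-12)) out <- out[-nrow(out), , drop = FALSE]
  out
}

# Tail of a polyline from arc length s to its end; first vertex interpolated.
polyline_clip_tail <- function(pts, s) {
  cl <- polyline_cumlen(pts)
  L <- cl[length(cl)]
  if (s <= 0) return(pts)
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  p <- polyline_point_at(pts, s)
  out <- rbind(p, pts[seq(i + 1L, nrow(pts)), , drop = FALSE])
  if (nrow(out) >= 2L && all(abs(out[2L, ] - p) < 1e-12)) out <- out[-1L, , drop = FALSE]
  out
}

# Nearest point on segment (ax,ay)-(bx,by) to p; returns c(x, y, t) with
# t in [0,1] the parameter along the segment.
nearest_on_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  t <- if (L2 > 0) ((px - ax) * dx + (py - ay) * dy) / L2 else 0
  t <- min(max(t, 0), 1)
  c(ax + t * dx, ay + t * dy, t)
}

# Nearest point on a polyline to p: list(point, dist, arc) where arc is the
# arc length from the polyline start to the nearest point.
nearest_on_polyline <- function(pts, px, py) {
  cl <- polyline_cumlen(pts)
  best <- list(point = pts[1, ], dist = Inf, arc = 0)
  for (i in seq_len(nrow(pts) - 1L)) {
    np <- nearest_on_segment(px, py, pts[i, 1], pts[i, 2], pts[i + 1L, 1], pts[i + 1L, 2])
    d <- sqrt((px - np[1])^2 + (py - np[2])^2)
    if (d < best$dist) {
      seglen <- cl[i + 1L] - cl[i]
      best <- list(point = np[1:2], dist = d, arc = cl[i] + np[3] * seglen)
    }
  }
  best
}

# Do segments p1-p2 and p3-p4 intersect (including touching)?
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  on_seg <- function(a, b, c)
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (abs(d1) < 1e-12 && on_seg(p3, p4, p1)) || (abs(d2) < 1e-12 && on_seg(p3, p4, p2)) ||
    (abs(d3) < 1e-12 && on_seg(p1, p2, p3)) || (abs(d4) < 1e-12 && on_seg(p1, p2, p4))
}

# Even-odd (ray casting) point-in-polygon; boundary points count as inside.
point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    # boundary check
    np <- nearest_on_segment(px, py, xi, yi, xj, yj)
    if (sqrt((px - np[1])^2 + (py - np[2])^2) < 1e-9) return(TRUE)
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Vectorised even-odd test for many points against one ring (no boundary
# special-casing; used for rasterisation where centres rarely sit on edges).
points_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) / (yj - yi) * (xj - xi)
      hit <- px[crosses] < xint
      inside[crosses][hit] <- !inside[crosses][hit]
    }
    j <- i
  }
  inside
}

# Does a polyline intersect a polygon (any vertex inside, or any edge pair
# crossing)?
polyline_intersects_polygon <- function(pts, ring) {
  for (i in seq_len(nrow(pts)))
    if (point_in_polygon(pts[i, 1], pts[i, 2], ring)) return(TRUE)
  nr <- nrow(ring)
  for (i in seq_len(nrow(pts) - 1L)) {
    j <- nr
    for (k in seq_len(nr)) {
      if (segments_intersect(pts[i, ], pts[i + 1L, ], ring[k, ], ring[j, ])) return(TRUE)
      j <- k
    }
  }
  FALSE
}

# Does segment a-b intersect the axis-aligned rectangle [xmin,xmax]x[ymin,ymax]?
segment_intersects_rect <- function(ax, ay, bx, by, xmin, xmax, ymin, ymax) {
  inside <- function(x, y) x >= xmin - 1e-12 && x <= xmax + 1e-12 && y >= ymin - 1e-12 && y <= ymax + 1e-12
  if (inside(ax, ay) || inside(bx, by)) return(TRUE)
  corners <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  for (i in 1:4) {
    j <- if (i == 4L) 1L else i + 1L
    if (segments_intersect(c(ax, ay), c(bx, by), corners[i, ], corners[j, ])) return(TRUE)
  }
  FALSE
}

# ---- GeoJSON I/O --------------------------------------------------------

#' Read a GeoJSON FeatureCollection
#'
#' Supports Point, LineString, MultiLineString and Polygon geometries.
#'
#' @param path a `.geojson`/`.json` file.
#' @return list with `geoms` (list of xy matrices; polygons keep only their
#'   outer ring), `type` (character per feature) and `properties`
#'   (data.frame, one row per feature).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  geoms <- list(); types <- character(0); props <- list()
  to_mat <- function(coords) do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  for (f in feats) {
    g <- f$geometry
    ty <- g$type
    m <- switch(ty,
      Point = matrix(unlist(g$coordinates)[1:2], ncol = 2),
      LineString = to_mat(g$coordinates),
      MultiLineString = to_mat(g$coordinates[[1]]),  # first part; parts rarely used here
      Polygon = to_mat(g$coordinates[[1]]),
      stop("unsupported GeoJSON geometry type: ", ty))
    geoms[[length(geoms) + 1L]] <- m
    types <- c(types, ty)
    props[[length(props) + 1L]] <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
  }
  pdf <- if (length(props) && length(props[[1]]))
    do.call(rbind, lapply(props, function(p) as.data.frame(p, stringsAsFactors = FALSE)))
  else data.frame(row.names = seq_along(geoms))
  list(geoms = geoms, type = types, properties = pdf)
}

#' Write a GeoJSON FeatureCollection
#'
#' @param geoms list of xy matrices (a 1-row matrix becomes a Point).
#' @param type geometry type for each feature: "Point", "LineString" or
#'   "Polygon" (recycled).
#' @param properties optional data.frame of per-feature attributes.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geoms, type, path, properties = NULL) {
  type <- rep_len(type, length(geoms))
  feats <- lapply(seq_along(geoms), function(i) {
    m <- geoms[[i]]
    coords <- switch(type[i],
      Point = as.list(as.numeric(m[1, ])),
      LineString = lapply(seq_len(nrow(m)), function(r) as.list(as.numeric(m[r, ]))),
      Polygon = {
        ring <- m
        if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
        list(lapply(seq_len(nrow(ring)), function(r) as.list(as.numeric(ring[r, ]))))
      },
      stop("unsupported type: ", type[i]))
    pr <- if (!is.null(properties) && ncol(properties))
      lapply(as.list(properties[i, , drop = FALSE]), jsonlite::unbox)
    else structure(list(), names = character(0))
    list(type = jsonlite::unbox("Feature"),
         geometry = list(type = jsonlite::unbox(type[i]), coordinates = coords),
         properties = pr)
  })
  jsonlite::write_json(list(type = jsonlite::unbox("FeatureCollection"), features = feats),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
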