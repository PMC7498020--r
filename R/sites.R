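# Site handling: snapping observation points onto the network, generating
# evenly spaced prediction sites, and expanding repeated measurements.
#
# Positional conventions (used consistently by the predictor attribution and
# the .ssn export):
#   ratio  — position along the edge measured from its DOWNSTREAM junction,
#            in [0, 1] (0 = at the junction, 1 = at the upstream node);
#   upDist — along-network distance from the network outlet to the site:
#            upDist(site) = upDist(edge) - length(edge) + ratio * length(edge).

#' Snap sites to the stream network
#'
#' Moves each point to the nearest point on any non-artificial edge
#' geometry (exhaustive minimisation over all edge segments; ties between
#' equidistant edges go to the smaller rid). Points farther than `max_dist`
#' from every edge are dropped and reported. The `dist_moved` column
#' (exported as 'dist') is the Euclidean snap distance in map units.
#'
#' @param points data.frame with columns `x`, `y` (any other columns are
#'   carried through), or a [read_geojson()] result of a point layer.
#' @param net a `stream_network`.
#' @param max_dist maximum allowed snap distance (m), `> 0`.
#' @return list with `sites` (snapped data.frame: pid, locID, rid, netID,
#'   x, y, orig_x, orig_y, dist_moved, ratio, upDist_m + carried columns)
#'   and `dropped` (input row indices that exceeded `max_dist`).
#' @export
snap_sites <- function(points, net, max_dist) {
  if (!is.numeric(max_dist) || max_dist <= 0) stop("max_dist must be > 0")
  if (is.list(points) && !is.null(points$geoms)) {
    xy <- do.call(rbind, points$geoms)
    pts <- cbind(data.frame(x = xy[, 1], y = xy[, 2]), points$properties)
  } else pts <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(pts))) stop("points need x and y columns")
  e <- net$edges[!net$edges$artificial, , drop = FALSE]
  if (!nrow(e)) stop("empty network")
  n <- nrow(pts)
  out <- data.frame(pid = NA_integer_, locID = NA_integer_,
                    rid = NA_integer_, netID = NA_integer_,
                    x = NA_real_, y = NA_real_,
                    orig_x = pts$x, orig_y = pts$y,
                    dist_moved = NA_real_, ratio = NA_real_, upDist_m = NA_real_)
  for (i in seq_len(n)) {
    best_d <- Inf; best_rid <- NA_integer_; best <- NULL
    for (j in seq_len(nrow(e))) {
      g <- net$geoms[[as.character(e$rid[j])]]
      np <- nearest_on_polyline(g, pts$x[i], pts$y[i])
      if (np$dist < best_d - 1e-12 ||
          (abs(np$dist - best_d) <= 1e-12 && e$rid[j] < best_rid)) {
        best_d <- np$dist; best_rid <- e$rid[j]; best <- np
      }
    }
    if (best_d > max_dist) next
    j <- match(best_rid, e$rid)
    L <- e$length_m[j]
    ratio <- if (L > 0) (L - best$arc) / L else 0
    out$rid[i] <- best_rid
    out$netID[i] <- e$netID[j]
    out$x[i] <- best$point[1]; out$y[i] <- best$point[2]
    out$dist_moved[i] <- best_d
    out$ratio[i] <- ratio
    out$upDist_m[i] <- e$upDist_m[j] - L + ratio * L
  }
  dropped <- which(is.na(out$rid))
  kept <- setdiff(seq_len(n), dropped)
  out <- out[kept, , drop = FALSE]
  out$locID <- seq_len(nrow(out))
  out$pid <- out$locID
  extra <- setdiff(names(pts), c("x", "y"))
  for (cn in extra) out[[cn]] <- pts[[cn]][kept]
  rownames(out) <- NULL
  if (length(dropped))
    message(sprintf("snap_sites: dropped %d site(s) beyond max_dist = %g m (rows %s)",
                    length(dropped), max_dist, paste(dropped, collapse = ",")))
  list(sites = out, dropped = dropped)
}

#' Generate evenly spaced prediction sites
#'
#' Places sites along every selected network at a constant along-network
#' spacing `s`, phase-shifted so the first site sits at `s/2` from the
#' outlet: a site is placed at every point whose along-network distance from
#' the outlet equals `s/2 + k*s`. Above a confluence both branches continue
#' the same distance sequence, so consecutive sites along any unbranched
#' path are exactly `s` apart.
#'
#' @param net a `stream_network`.
#' @param n_sites desired number of sites; `s` is then the total selected
#'   stream length divided by `n_sites`. Give exactly one of
#'   `n_sites`/`spacing_m`.
#' @param spacing_m along-network spacing in metres.
#' @param netIDs optional subset of networks.
#' @return data.frame of prediction sites (same columns as [snap_sites()]
#'   output; `dist_moved = 0`).
#' @export
generate_prediction_sites <- function(net, n_sites = NULL, spacing_m = NULL, netIDs = NULL) {
  if (is.null(n_sites) == is.null(spacing_m))
    stop("give exactly one of n_sites / spacing_m")
  e <- net$edges
  if (!is.null(netIDs)) e <- e[e$netID %in% netIDs, , drop = FALSE]
  if (!nrow(e)) stop("no edges in the selected networks")
  total <- sum(e$length_m)
  s <- if (!is.null(spacing_m)) {
    if (spacing_m <= 0) stop("spacing_m must be > 0")
    spacing_m
  } else {
    if (n_sites < 1) stop("n_sites must be >= 1")
    total / n_sites
  }
  if (s > max(tapply(e$length_m, e$netID, sum)))
    warning("spacing exceeds the longest selected network; zero sites possible")
  rows <- list()
  for (j in seq_len(nrow(e))) {
    L <- e$length_m[j]
    d1 <- e$upDist_m[j]          # distance outlet -> upstream node
    d0 <- d1 - L                 # distance outlet -> downstream node
    if (L <= 0) next
    k0 <- ceiling((d0 - s / 2) / s + 1e-12)
    k0 <- max(k0, 0)
    dd <- s / 2 + k0 * s
    while (dd <= d1 + 1e-9) {
      if (dd > d0 + 1e-9) {
        ratio <- (dd - d0) / L
        g <- net$geoms[[as.character(e$rid[j])]]
        p <- polyline_point_at(g, L - (dd - d0))
        rows[[length(rows) + 1L]] <- data.frame(
          pid = NA_integer_, locID = NA_integer_, rid = e$rid[j], netID = e$netID[j],
          x = p[1], y = p[2], orig_x = p[1], orig_y = p[2],
          dist_moved = 0, ratio = ratio, upDist_m = dd)
      }
      dd <- dd + s
    }
  }
  if (!length(rows)) {
    warning("no prediction sites generated")
    return(data.frame(pid = integer(0), locID = integer(0), rid = integer(0),
                      netID = integer(0), x = numeric(0), y = numeric(0),
                      orig_x = numeric(0), orig_y = numeric(0),
                      dist_moved = numeric(0), ratio = numeric(0), upDist_m = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$netID, out$upDist_m, out$rid), , drop = FALSE]
  out$locID <- seq_len(nrow(out))
  out$pid <- out$locID
  rownames(out) <- NULL
  out
}

#' Merge repeated measurements onto sites
#'
#' Expands the site table to one record per measurement row: every matched
#' measurement duplicates its location's coordinates, rid, ratio, upDist and
#' static attributes; `pid` is reassigned uniquely 1..N while `locID` is
#' preserved per location, so repeated measurements share a locID.
#'
#' @param sites snapped sites (from [snap_sites()]).
#' @param table measurement data.frame (e.g. `read.csv` output).
#' @param site_key name of the column in `table` holding the site `locID`
#'   (or the name of a site identifier column present in `sites`).
#' @return data.frame of measurement records.
#' @export
merge_sites_with_measurements <- function(sites, table, site_key) {
  if (!site_key %in% names(table))
    stop(sprintf("key column '%s' missing from the measurement table", site_key))
  key_col <- if (site_key %in% names(sites) && site_key != "locID") sites[[site_key]] else sites$locID
  si <- match(table[[site_key]], key_col)
  unmatched <- which(is.na(si))
  if (length(unmatched)) {
    warning(sprintf("merge_sites_with_measurements: %d unmatched measurement row(s): keys %s",
                    length(unmatched),
                    paste(unique(table[[site_key]][unmatched]), collapse = ",")))
    table <- table[!is.na(si), , drop = FALSE]
    si <- si[!is.na(si)]
  }
  out <- sites[si, , drop = FALSE]
  meas_cols <- setdiff(names(table), site_key)
  for (cn in meas_cols) {
    nm <- if (cn %in% names(out)) paste0(cn, "_meas") else cn
    out[[nm]] <- table[[cn]]
  }
  out$pid <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
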