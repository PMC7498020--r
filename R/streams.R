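# Stream network extraction and topology.
#
# A stream_network is a forest of in-trees: every edge is a directed stream
# segment (upstream node -> downstream node), each connected network has one
# outlet, and after correct_complex_confluences() every confluence has
# exactly two inflows — the admissibility conditions required by spatial
# stream-network (SSN) models. binaryIDs encode tree position ("1" at the
# outlet edge, one appended character per branching level).

#' Extract the stream raster from flow accumulation
#'
#' Cells with accumulation `>= accum_threshold` become stream cells, then the
#' stream cells are partitioned into segments between topological
#' breakpoints (sources, confluences, outlets) along D8 paths. Headwater
#' segments shorter than `min_stream_length` cells are pruned, iteratively
#' until stable (pruning a spur may merge the two segments it separated).
#'
#' @param acc accumulation grid from [accumulate()].
#' @param fd the `flow_dir` the accumulation was computed on.
#' @param accum_threshold minimum accumulated cells to delineate a stream
#'   (>= 1).
#' @param min_stream_length minimum headwater segment length in cells.
#' @return A [raster_grid()] whose values are per-cell segment ids (0 = not
#'   a stream cell).
#' @export
extract_streams <- function(acc, fd, accum_threshold, min_stream_length = 0) {
  stopifnot(inherits(acc, "raster_grid"))
  if (accum_threshold < 1) stop("accum_threshold must be >= 1")
  if (min_stream_length < 0) stop("min_stream_length must be >= 0")
  n <- fd$nrows * fd$ncols
  is_stream <- !is.na(acc$values) & acc$values >= accum_threshold & !is.na(fd$d8)
  if (!any(is_stream)) stop("no streams at this threshold")
  repeat {
    seg <- label_stream_segments(is_stream, fd)
    if (min_stream_length <= 0) break
    lens <- tabulate(seg$sid[seg$sid > 0])
    short_head <- which(seg$headwater & lens < min_stream_length)
    if (!length(short_head)) break
    is_stream[seg$sid %in% short_head] <- FALSE
    if (!any(is_stream)) stop("no streams left after pruning; lower min_stream_length")
  }
  out <- raster_grid(matrix(as.numeric(seg$sid), fd$nrows, fd$ncols),
                     cell_size = fd$cell_size, origin_x = fd$origin_x,
                     origin_y = fd$origin_y, crs_tag = fd$crs_tag)
  out
}

# Unit map-direction (dx, dy) from a boundary/nodata-adjacent cell toward
# off-grid, preferring cardinal sides in canonical neighbour order.
exit_direction <- function(fd, cell) {
  nr <- fd$nrows; nc <- fd$ncols
  col <- (cell - 1L) %/% nr + 1L; row <- cell - (col - 1L) * nr
  offs <- nbr_offsets()
  for (k in c(1L, 3L, 5L, 7L, 2L, 4L, 6L, 8L)) {   # E, S, W, N first
    o <- offs[[k]]
    rr <- row + o[1]; cc <- col + o[2]
    off_grid <- rr < 1L || rr > nr || cc < 1L || cc > nc
    if (off_grid || is.na(fd$d8[(cc - 1L) * nr + rr]))
      return(c(o[2], -o[1]) / sqrt(sum(o^2)))       # (dcol, -drow) in map x/y
  }
  c(0, -1)  # fallback: due south
}

# Partition stream cells into segments. Returns sid (matrix-shaped integer
# vector, 0 off-stream), and per-segment bookkeeping. A junction cell (>= 2
# stream inflows) belongs to the segment downstream of the junction.
label_stream_segments <- function(is_stream, fd) {
  n <- fd$nrows * fd$ncols
  tgt <- fd$target
  scells <- which(is_stream)
  ds <- tgt[scells]                      # downstream cell, any
  ds[!is.na(ds) & !is_stream[ds]] <- NA  # only in-stream links count
  ds_full <- rep(NA_integer_, n); ds_full[scells] <- ds
  inflow <- integer(n)
  has_ds <- scells[!is.na(ds)]
  if (length(has_ds)) {
    tb <- table(ds_full[has_ds])
    inflow[as.integer(names(tb))] <- as.integer(tb)
  }
  starts <- scells[inflow[scells] != 1L]
  sid <- integer(n)
  headwater <- logical(length(starts))
  k <- 0L
  # deterministic: starts in scan (cell-index) order
  for (s in sort(starts)) {
    k <- k + 1L
    headwater[k] <- inflow[s] == 0L
    cur <- s
    repeat {
      sid[cur] <- k
      nxt <- ds_full[cur]
      if (is.na(nxt) || inflow[nxt] != 1L) break
      cur <- nxt
    }
  }
  list(sid = sid, headwater = headwater[seq_len(k)], ds_full = ds_full, inflow = inflow)
}

#' Vectorize a stream raster into a topological network
#'
#' Each maximal stream path between breakpoints becomes one directed edge
#' with geometry through cell centres; the junction cell's centre is the
#' shared node. Reach contributing areas (RCAs) are delineated on D8 — every
#' non-stream cell is assigned to the segment owning the first stream cell
#' on its D8 path — so RCA cell sets are disjoint and areas are exactly
#' additive. Networks (netIDs) are numbered by outlet coordinates,
#' south-most then west-most first; edge rids are assigned in scan order,
#' starting at 0.
#'
#' @param streams stream raster from [extract_streams()].
#' @param fd the `flow_dir` used for extraction.
#' @param dem the (filled) DEM, for provenance/CRS.
#' @return A `stream_network` object.
#' @export
vectorize <- function(streams, fd, dem) {
  nr <- fd$nrows; nc <- fd$ncols; n <- nr * nc
  cs <- fd$cell_size
  is_stream <- !is.na(streams$values) & streams$values > 0
  if (!any(is_stream)) stop("empty stream raster")
  seg <- label_stream_segments(is_stream, fd)
  sid <- seg$sid; ds_full <- seg$ds_full; inflow <- seg$inflow
  nseg <- max(sid)
  # ordered cells per segment
  scells <- which(sid > 0)
  starts <- scells[inflow[scells] != 1L]
  seg_cells <- vector("list", nseg)
  seg_ds_cell <- rep(NA_integer_, nseg)
  for (s in sort(starts)) {
    id <- sid[s]
    chain <- integer(0)
    cur <- s
    repeat {
      chain <- c(chain, cur)
      nxt <- ds_full[cur]
      if (is.na(nxt) || inflow[nxt] != 1L) { seg_ds_cell[id] <- nxt; break }
      cur <- nxt
    }
    seg_cells[[id]] <- chain
  }
  grid_meta <- list(nrows = nr, ncols = nc, cell_size = cs,
                    origin_x = fd$origin_x, origin_y = fd$origin_y,
                    crs_tag = fd$crs_tag)
  gtmpl <- structure(c(grid_meta, list(values = NULL)), class = "raster_grid")
  # nodes: one per segment start cell (source/confluence), plus a distinct
  # outlet node per outlet segment (distinct even if the segment has a
  # single cell, so no edge can become a self-loop)
  node_cell <- integer(0); node_kind <- character(0)
  for (id in seq_len(nseg)) {
    first <- seg_cells[[id]][1L]
    node_cell <- c(node_cell, first)
    node_kind <- c(node_kind, if (inflow[first] >= 2L) "confluence" else "source")
  }
  node_of_cell <- integer(n)
  node_of_cell[node_cell] <- seq_along(node_cell)
  outlet_segs <- which(is.na(seg_ds_cell))
  outlet_node_of_seg <- rep(NA_integer_, nseg)
  for (id in outlet_segs) {
    node_cell <- c(node_cell, seg_cells[[id]][length(seg_cells[[id]])])
    node_kind <- c(node_kind, "outlet")
    outlet_node_of_seg[id] <- length(node_cell)
  }
  node_xy <- cell_xy(gtmpl, node_cell)
  nodes <- data.frame(node_id = seq_along(node_cell),
                      x = node_xy[, 1], y = node_xy[, 2],
                      kind = node_kind, stringsAsFactors = FALSE)
  # rid in scan order of segment start cells = segment id order
  rid <- seq_len(nseg) - 1L
  geoms <- vector("list", nseg)
  from_node <- to_node <- integer(nseg)
  for (id in seq_len(nseg)) {
    cells <- seg_cells[[id]]
    pts <- cell_xy(gtmpl, cells)
    dsc <- seg_ds_cell[id]
    if (!is.na(dsc)) pts <- rbind(pts, cell_xy(gtmpl, dsc))
    if (nrow(pts) == 1L) {
      # single-cell outlet segment: extend half a cell toward the off-grid
      # exit so the edge has positive length and distinct end nodes
      pts <- rbind(pts, pts[1, ] + 0.5 * cs * exit_direction(fd, cells[length(cells)]))
    }
    geoms[[id]] <- unname(pts)
    from_node[id] <- node_of_cell[cells[1L]]
    to_node[id] <- if (!is.na(dsc)) node_of_cell[dsc] else outlet_node_of_seg[id]
  }
  # netID: component root per segment, numbered south-most then west-most
  seg_ds_seg <- ifelse(is.na(seg_ds_cell), NA_integer_, sid[pmax(seg_ds_cell, 1L)])
  root <- seq_len(nseg)
  repeat {
    nxt <- ifelse(is.na(seg_ds_seg[root]), root, seg_ds_seg[root])
    if (all(nxt == root)) break
    root <- nxt
  }
  ocell <- vapply(root, function(r) seg_cells[[r]][length(seg_cells[[r]])], integer(1))
  oxy <- cell_xy(gtmpl, vapply(outlet_segs, function(r) seg_cells[[r]][length(seg_cells[[r]])], integer(1)))
  oord <- order(oxy[, 2], oxy[, 1])  # south-most (min y) then west-most
  net_of_root <- integer(nseg)
  net_of_root[outlet_segs[oord]] <- seq_along(outlet_segs)
  netID <- net_of_root[root]
  # RCA: first stream segment hit along the D8 path, cells processed upslope
  lab <- integer(n)
  live <- which(!is.na(fd$d8))
  ord <- live[order(fd$elev[live])]  # ascending: downstream cells first
  tgt <- fd$target
  for (i in ord) {
    if (sid[i] > 0L) lab[i] <- sid[i]
    else {
      t <- tgt[i]
      lab[i] <- if (is.na(t)) 0L else lab[t]
    }
  }
  rca <- vector("list", nseg)
  labbed <- which(lab > 0L)
  sp <- split(labbed, lab[labbed])
  rca[as.integer(names(sp))] <- sp
  for (id in seq_len(nseg)) if (is.null(rca[[id]])) rca[[id]] <- integer(0)
  km2 <- cs * cs / 1e6
  edges <- data.frame(
    rid = rid, netID = netID, from_node = from_node, to_node = to_node,
    length_m = vapply(geoms, polyline_length, numeric(1)),
    upDist_m = NA_real_, binaryID = NA_character_, shreve = NA_integer_,
    rca_km2 = vapply(rca, length, integer(1)) * km2,
    h2o_km2 = NA_real_, artificial = FALSE, stringsAsFactors = FALSE)
  names(geoms) <- names(rca) <- as.character(rid)
  cells_l <- seg_cells
  names(cells_l) <- as.character(rid)
  net <- structure(list(edges = edges, geoms = geoms, rca = rca,
                        cells = cells_l, nodes = nodes, grid = grid_meta,
                        attr_cols = character(0)),
                   class = "stream_network")
  recompute_network(net)
}

#' @export
print.stream_network <- function(x, ...) {
  cat(sprintf("<stream_network> %d edges, %d nodes, %d network(s)\n",
              nrow(x$edges), nrow(x$nodes), length(unique(x$edges$netID))))
  cat(sprintf("  total length %.1f m, outlet catchment(s) %.4f km2\n",
              sum(x$edges$length_m), sum(outlet_edges(x)$h2o_km2)))
  invisible(x)
}

# Edges that are network outlets (their to_node has no outflowing edge).
outlet_edges <- function(net) {
  e <- net$edges
  e[!(e$to_node %in% e$from_node), , drop = FALSE]
}

# rids of the (up to 2, pre-correction possibly more) edges flowing into
# each edge's upstream node; list parallel to net$edges rows, sorted by rid.
prev_rids <- function(net) {
  e <- net$edges
  lapply(e$from_node, function(fn) sort(e$rid[e$to_node == fn]))
}

#' Recompute derived topology attributes
#'
#' Recomputes edge lengths, Shreve magnitude, cumulative catchment areas
#' (`h2o_km2 = rca_km2 + sum of upstream h2o_km2`), upstream distances
#' (`upDist` of an edge = along-network distance from the network outlet to
#' the edge's upstream node; the outlet edge's upDist equals its own length)
#' and binaryIDs. binaryIDs are left `NA` for networks that still contain a
#' complex confluence.
#'
#' @param net a `stream_network`.
#' @return The network with refreshed derived columns.
#' @export
recompute_network <- function(net) {
  e <- net$edges
  m <- nrow(e)
  e$length_m <- vapply(e$rid, function(r) polyline_length(net$geoms[[as.character(r)]]), numeric(1))
  km2 <- net$grid$cell_size^2 / 1e6
  e$rca_km2 <- vapply(e$rid, function(r) length(net$rca[[as.character(r)]]), integer(1)) * km2
  prev <- prev_rids_for(e)
  idx_of_rid <- seq_len(m); names(idx_of_rid) <- as.character(e$rid)
  # post-order (upstream first) per network via explicit stack from outlets
  e$shreve <- NA_integer_; e$h2o_km2 <- NA_real_
  e$upDist_m <- NA_real_; e$binaryID <- NA_character_
  out_idx <- which(!(e$to_node %in% e$from_node))
  for (oi in out_idx) {
    # iterative post-order
    stack <- list(c(oi, 0L))
    order_post <- integer(0)
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- top[1]
      order_post <- c(i, order_post)   # reverse pre-order = post-order for trees
      for (pr in prev[[i]]) stack[[length(stack) + 1L]] <- c(idx_of_rid[[as.character(pr)]], 0L)
    }
    for (i in order_post) {
      ps <- prev[[i]]
      if (!length(ps)) {
        e$shreve[i] <- 1L
        e$h2o_km2[i] <- e$rca_km2[i]
      } else {
        pidx <- idx_of_rid[as.character(ps)]
        e$shreve[i] <- sum(e$shreve[pidx])
        e$h2o_km2[i] <- e$rca_km2[i] + sum(e$h2o_km2[pidx])
      }
    }
    # downstream-up pass: upDist and binaryID
    complex_here <- any(vapply(order_post, function(i) length(prev[[i]]) > 2L, logical(1)))
    e$upDist_m[oi] <- e$length_m[oi]
    if (!complex_here) e$binaryID[oi] <- "1"
    queue <- oi
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      ps <- prev[[i]]
      if (!length(ps)) next
      pidx <- idx_of_rid[as.character(ps)]
      for (j in pidx) e$upDist_m[j] <- e$upDist_m[i] + e$length_m[j]
      if (!complex_here) {
        if (length(pidx) == 1L) {
          e$binaryID[pidx] <- paste0(e$binaryID[i], "1")
        } else {
          # larger cumulative area gets "1"; tie -> smaller rid gets "1"
          o2 <- order(-e$h2o_km2[pidx], e$rid[pidx])
          e$binaryID[pidx[o2[1]]] <- paste0(e$binaryID[i], "1")
          e$binaryID[pidx[o2[2]]] <- paste0(e$binaryID[i], "0")
        }
      }
      queue <- c(queue, as.list(pidx))
    }
  }
  net$edges <- e
  net
}

prev_rids_for <- function(e) {
  lapply(e$from_node, function(fn) sort(e$rid[e$to_node == fn]))
}

#' Find complex confluences
#'
#' Nodes receiving three or more inflowing segments (and a single outflow) —
#' inadmissible for SSN modelling. An empty result means the network is
#' admissible in this respect.
#'
#' @param net a `stream_network`.
#' @return Integer vector of offending node ids (possibly empty).
#' @export
check_complex_confluences <- function(net) {
  counts <- table(net$edges$to_node)
  sort(as.integer(names(counts)[counts >= 3L]))
}

#' Correct complex confluences
#'
#' For each node with three or more inflows, repeatedly takes the two
#' smallest-rid inflows, moves their junction a small step upstream to a new
#' pseudo node placed on the smallest-rid inflow's geometry at
#' `offset_fraction * cell_size` before the old node, and inserts a tiny
#' artificial segment from the pseudo node to the old node. The artificial
#' edge carries no reach contributing area, so catchment areas are conserved
#' exactly. Repeats until every confluence has exactly two inflows, then
#' recomputes the derived topology (binaryID, upDist, Shreve, h2o).
#'
#' A node with `k >= 3` inflows gains exactly `k - 2` artificial edges.
#'
#' @param net a `stream_network`.
#' @param offset_fraction stub length as a fraction of the cell size, in
#'   `(0, 0.5]`.
#' @return The corrected `stream_network`.
#' @export
correct_complex_confluences <- function(net, offset_fraction = 0.25) {
  if (!is.numeric(offset_fraction) || offset_fraction <= 0 || offset_fraction > 0.5)
    stop("offset_fraction must be in (0, 0.5]")
  bad <- check_complex_confluences(net)
  if (!length(bad)) return(net)
  cs <- net$grid$cell_size
  for (nd in bad) {
    repeat {
      e <- net$edges
      inflows <- sort(e$rid[e$to_node == nd])
      if (length(inflows) <= 2L) break
      a <- inflows[1]; b <- inflows[2]
      ia <- match(a, e$rid); ib <- match(b, e$rid)
      off <- offset_fraction * cs
      La <- e$length_m[ia]
      if (La <= off) off <- La / 2
      ga <- net$geoms[[as.character(a)]]
      head_g <- polyline_clip_head(ga, La - off)
      tail_g <- polyline_clip_tail(ga, La - off)
      vprime <- head_g[nrow(head_g), ]
      pid <- max(net$nodes$node_id) + 1L
      net$nodes <- rbind(net$nodes,
                         data.frame(node_id = pid, x = vprime[1], y = vprime[2],
                                    kind = "pseudo", stringsAsFactors = FALSE))
      net$geoms[[as.character(a)]] <- head_g
      net$edges$to_node[ia] <- pid
      gb <- net$geoms[[as.character(b)]]
      gb[nrow(gb), ] <- vprime
      net$geoms[[as.character(b)]] <- gb
      net$edges$to_node[ib] <- pid
      new_rid <- max(net$edges$rid) + 1L
      net$edges <- rbind(net$edges, data.frame(
        rid = new_rid, netID = net$edges$netID[ia], from_node = pid, to_node = nd,
        length_m = polyline_length(tail_g), upDist_m = NA_real_,
        binaryID = NA_character_, shreve = NA_integer_, rca_km2 = 0,
        h2o_km2 = NA_real_, artificial = TRUE, stringsAsFactors = FALSE))
      net$geoms[[as.character(new_rid)]] <- tail_g
      net$rca[[as.character(new_rid)]] <- integer(0)
      net$cells[[as.character(new_rid)]] <- integer(0)
    }
  }
  recompute_network(net)
}

#' Sever stream networks at lakes
#'
#' Removes every edge whose geometry intersects a lake polygon; upstream
#' subtrees cut off from their outlet become new, separate networks with
#' fresh netIDs (existing networks that keep their outlet keep their netID).
#' Removed rids are retired, never reused. Derived topology (binaryID,
#' upDist, Shreve, h2o) is recomputed per network.
#'
#' @param net a `stream_network`.
#' @param lakes list of polygon rings (2-column xy matrices), or a
#'   [read_geojson()] result.
#' @return The modified `stream_network`.
#' @export
delete_lakes <- function(net, lakes) {
  if (is.list(lakes) && !is.null(lakes$geoms)) lakes <- lakes$geoms
  if (!length(lakes)) return(net)
  hit <- vapply(net$edges$rid, function(r) {
    g <- net$geoms[[as.character(r)]]
    any(vapply(lakes, function(ring) polyline_intersects_polygon(g, ring), logical(1)))
  }, logical(1))
  if (!any(hit)) return(net)
  e <- net$edges
  old_outlet_rids <- outlet_edges(net)$rid
  keep <- e[!hit, , drop = FALSE]
  rm_rids <- e$rid[hit]
  ch <- as.character(keep$rid)
  net$geoms <- net$geoms[ch]; net$rca <- net$rca[ch]; net$cells <- net$cells[ch]
  # downstream edge among kept edges
  ds_rid <- vapply(seq_len(nrow(keep)), function(i) {
    cand <- keep$rid[keep$from_node == keep$to_node[i]]
    if (length(cand)) cand[1] else NA_integer_
  }, integer(1))
  root <- seq_len(nrow(keep))
  repeat {
    nxt <- ifelse(is.na(ds_rid[root]), root, match(ds_rid[root], keep$rid))
    if (all(nxt == root)) break
    root <- nxt
  }
  root_rid <- keep$rid[root]
  # netID policy: original outlets keep their netID; severed roots get fresh
  new_net <- integer(nrow(keep))
  surviving <- intersect(unique(root_rid), old_outlet_rids)
  for (r in surviving) new_net[root_rid == r] <- keep$netID[match(r, keep$rid)]
  fresh_roots <- setdiff(unique(root_rid), surviving)
  if (length(fresh_roots)) {
    oxy <- t(vapply(fresh_roots, function(r) {
      g <- net$geoms[[as.character(r)]]; g[nrow(g), ]
    }, numeric(2)))
    fresh_roots <- fresh_roots[order(oxy[, 2], oxy[, 1])]
    next_id <- max(e$netID) + 1L
    for (r in fresh_roots) {
      new_net[root_rid == r] <- next_id
      next_id <- next_id + 1L
    }
  }
  keep$netID <- new_net
  # new outlet nodes
  new_outlets <- keep$to_node[keep$rid %in% setdiff(unique(root_rid), old_outlet_rids)]
  net$nodes$kind[net$nodes$node_id %in% new_outlets] <- "outlet"
  net$edges <- keep
  net <- recompute_network(net)
  message(sprintf("delete_lakes: removed %d edge(s) [rids %s]; %d network(s) now",
                  length(rm_rids), paste(rm_rids, collapse = ","),
                  length(unique(keep$netID))))
  net
}

#' Topological admissibility census
#'
#' Checks the conditions required by SSN models: no diverging nodes (a node
#' with two or more outflows), no converging nodes without an outflow other
#' than network outlets (an outlet node carries exactly one inflow), and no
#' complex confluences (three or more inflows).
#'
#' @param net a `stream_network`.
#' @return A list with logical `admissible` and character `problems`.
#' @export
admissibility_census <- function(net) {
  e <- net$edges
  problems <- character(0)
  outn <- table(e$from_node)
  div <- as.integer(names(outn)[outn >= 2L])
  if (length(div)) problems <- c(problems, sprintf("diverging node(s): %s", paste(div, collapse = ",")))
  # converging/complex nodes are judged within each network: after a lake
  # cut, two severed in-trees may share an outlet point without being
  # topologically connected
  for (nid in unique(e$netID)) {
    sub <- e[e$netID == nid, ]
    inn <- table(sub$to_node)
    cx <- as.integer(names(inn)[inn >= 3L])
    if (length(cx)) problems <- c(problems, sprintf("complex confluence(s): %s", paste(cx, collapse = ",")))
    sink_nodes <- setdiff(as.integer(names(inn)), sub$from_node)  # no outflow
    conv <- sink_nodes[inn[as.character(sink_nodes)] >= 2L]
    if (length(conv)) problems <- c(problems, sprintf("converging node(s) without outflow: %s", paste(conv, collapse = ",")))
    n_out <- sum(!(sub$to_node %in% sub$from_node))
    if (n_out != 1L) problems <- c(problems, sprintf("netID %d has %d outlets", nid, n_out))
  }
  list(admissible = length(problems) == 0L, problems = problems)
}
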