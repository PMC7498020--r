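# .ssn directory export/import: the on-disk bundle consumed by spatial
# stream-network modelling software — edges and sites as shapefile layers
# plus one per-network topology table of (rid, binaryID) pairs.

#' Export a `.ssn` directory
#'
#' Writes `edges.shp`, `sites.shp`, optionally `preds.shp` (each with
#' `.shx`/`.dbf` and, when a CRS is known, `.prj` sidecars) and one topology
#' table per network: a two-column comma-separated text file with header
#' `"rid","binaryID"`, binaryID quoted as text. Field names longer than the
#' 10-character DBF limit are abbreviated deterministically and the map is
#' written to `field_names.json`.
#'
#' The network must be admissible: no complex confluences (run
#' [correct_complex_confluences()] first) and binaryIDs computed.
#'
#' @param net a `stream_network`.
#' @param sites snapped observation sites (may be `NULL`).
#' @param preds prediction sites (may be `NULL`).
#' @param root output directory; conventionally ends in `.ssn`.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param net_file_style `"netID"` writes `netID1.dat`, `"net"` writes
#'   `net1.dat`.
#' @param layer_format `"shapefile"` (default) or `"geojson"`.
#' @return An `ssn_dataset` handle (list with `root` and layer names).
#' @export
export_ssn <- function(net, sites = NULL, preds = NULL, root, overwrite = FALSE,
                       net_file_style = c("netID", "net"),
                       layer_format = c("shapefile", "geojson")) {
  net_file_style <- match.arg(net_file_style)
  layer_format <- match.arg(layer_format)
  cx <- check_complex_confluences(net)
  if (length(cx))
    stop("inadmissible topology: complex confluence at node(s) ",
         paste(cx, collapse = ", "), "; run correct_complex_confluences() first")
  cen <- admissibility_census(net)
  if (!cen$admissible)
    stop("inadmissible topology: ", paste(cen$problems, collapse = "; "))
  if (anyNA(net$edges$binaryID)) stop("binaryIDs not computed; run recompute_network()")
  if (dir.exists(root) && length(dir(root)) && !overwrite)
    stop("directory exists and is not empty (use overwrite = TRUE): ", root)
  if (dir.exists(root) && overwrite) unlink(dir(root, full.names = TRUE), recursive = TRUE)
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  e <- net$edges
  prev <- prev_rids_for(e)
  edf <- data.frame(rid = as.numeric(e$rid), netID = as.numeric(e$netID),
                    binaryID = e$binaryID,
                    Length = e$length_m, upDist = e$upDist_m,
                    rcaAreaKm2 = e$rca_km2, H2OAreaKm2 = e$h2o_km2,
                    shreve = as.numeric(e$shreve),
                    prev_str01 = vapply(prev, function(p) if (length(p) >= 1) as.numeric(p[1]) else -1, numeric(1)),
                    prev_str02 = vapply(prev, function(p) if (length(p) >= 2) as.numeric(p[2]) else -1, numeric(1)),
                    stringsAsFactors = FALSE)
  for (cn in net$attr_cols) edf[[cn]] <- e[[cn]]
  geoms_e <- lapply(e$rid, function(r) net$geoms[[as.character(r)]])
  crs <- net$grid$crs_tag
  maps <- list()
  write_layer <- function(geoms, fields, nm, point) {
    am <- abbrev_fields(names(fields))
    maps[[nm]] <<- as.list(am)
    if (layer_format == "shapefile") {
      names(fields) <- unname(am)
      write_shapefile(geoms, fields, file.path(root, nm), point = point, crs_tag = crs)
    } else {
      write_geojson(geoms, if (point) "Point" else "LineString",
                    file.path(root, paste0(nm, ".geojson")), properties = fields)
    }
  }
  write_layer(geoms_e, edf, "edges", point = FALSE)
  if (!is.null(sites) && nrow(sites)) {
    sdf <- ssn_site_fields(sites)
    write_layer(lapply(seq_len(nrow(sites)), function(i) cbind(sites$x[i], sites$y[i])),
                sdf, "sites", point = TRUE)
  }
  if (!is.null(preds) && nrow(preds)) {
    pdf <- ssn_site_fields(preds)
    write_layer(lapply(seq_len(nrow(preds)), function(i) cbind(preds$x[i], preds$y[i])),
                pdf, "preds", point = TRUE)
  }
  for (nid in sort(unique(e$netID))) {
    sub <- e[e$netID == nid, , drop = FALSE]
    sub <- sub[order(sub$rid), ]
    fn <- file.path(root, sprintf("%s%d.dat", net_file_style, nid))
    writeLines(c("\"rid\",\"binaryID\"",
                 sprintf("%d,\"%s\"", sub$rid, sub$binaryID)), fn)
  }
  jsonlite::write_json(maps, file.path(root, "field_names.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(root = root,
                 layers = dir(root, pattern = "\\.(shp|geojson)$"),
                 net_file_style = net_file_style, layer_format = layer_format),
            class = "ssn_dataset")
}

ssn_site_fields <- function(sites) {
  df <- as.data.frame(sites, stringsAsFactors = FALSE)
  df <- df[vapply(df, function(col) is.numeric(col) || is.character(col), logical(1))]
  for (cn in c("pid", "locID", "rid", "netID")) if (cn %in% names(df)) df[[cn]] <- as.numeric(df[[cn]])
  if ("dist_moved" %in% names(df)) names(df)[names(df) == "dist_moved"] <- "dist"
  df$x <- NULL; df$y <- NULL
  df
}

#' Read and validate a `.ssn` directory
#'
#' Reconstructs the network topology from the per-network `.dat` tables and
#' the edge layer, validates the dataset invariants (every site rid exists
#' in edges; every netID has a table whose rids match the edge layer
#' exactly; one `"1"` binaryID root per network; parent/child binaryIDs
#' differ by exactly one appended character; no diverging, converging or
#' complex nodes) and errors on any violation.
#'
#' @param root a `.ssn` directory written by [export_ssn()].
#' @return list with `net` (a reconstructed `stream_network`; geometry and
#'   topology only, RCA cell sets are not stored on disk), `sites`, `preds`
#'   (data.frames or `NULL`).
#' @export
read_ssn <- function(root) {
  if (!dir.exists(root)) stop("no such .ssn directory: ", root)
  gj <- file.exists(file.path(root, "edges.geojson"))
  read_layer <- function(nm) {
    if (gj) {
      if (!file.exists(file.path(root, paste0(nm, ".geojson")))) return(NULL)
      r <- read_geojson(file.path(root, paste0(nm, ".geojson")))
      list(geoms = r$geoms, fields = r$properties)
    } else {
      if (!file.exists(file.path(root, paste0(nm, ".shp")))) return(NULL)
      r <- read_shapefile(file.path(root, nm))
      list(geoms = r$geoms, fields = r$fields)
    }
  }
  edges_l <- read_layer("edges")
  if (is.null(edges_l)) stop("missing edges layer in ", root)
  ef <- edges_l$fields
  need <- c("rid", "netID", "binaryID", "Length", "upDist")
  missing <- setdiff(need, names(ef))
  if (length(missing)) stop("edges layer lacks field(s): ", paste(missing, collapse = ", "))
  dat_files <- dir(root, pattern = "^net(ID)?[0-9]+\\.dat$", full.names = TRUE)
  if (!length(dat_files)) stop("no netX.dat topology tables in ", root)
  topo <- list()
  for (f in dat_files) {
    nid <- as.integer(sub("^net(ID)?([0-9]+)\\.dat$", "\\2", basename(f)))
    tab <- utils::read.csv(f, colClasses = c("integer", "character"))
    if (!identical(names(tab), c("rid", "binaryID")))
      stop("topology table ", basename(f), " must have columns rid,binaryID")
    topo[[as.character(nid)]] <- tab
  }
  sites_l <- read_layer("sites")
  preds_l <- read_layer("preds")
  err <- character(0)
  for (nid in unique(ef$netID)) {
    tab <- topo[[as.character(nid)]]
    if (is.null(tab)) { err <- c(err, sprintf("netID %d has no topology table", nid)); next }
    er <- sort(as.integer(ef$rid[ef$netID == nid]))
    orphan <- setdiff(tab$rid, as.integer(ef$rid))
    if (length(orphan)) err <- c(err, sprintf("orphan rid(s) %s in net%d table", paste(orphan, collapse = ","), nid))
    if (!identical(sort(as.integer(tab$rid)), er))
      err <- c(err, sprintf("netID %d: table rids do not match edge rids", nid))
    if (anyDuplicated(tab$rid)) err <- c(err, sprintf("netID %d: duplicated rid in table", nid))
    if (anyDuplicated(tab$binaryID)) err <- c(err, sprintf("netID %d: duplicated binaryID", nid))
    if (!any(tab$binaryID == "1")) err <- c(err, sprintf("netID %d: no outlet edge (missing binaryID \"1\")", nid))
  }
  for (nm in c("sites", "preds")) {
    l <- get(paste0(nm, "_l"))
    if (!is.null(l) && "rid" %in% names(l$fields)) {
      bad <- setdiff(l$fields$rid, ef$rid)
      if (length(bad)) err <- c(err, sprintf("%s reference unknown rid(s): %s", nm, paste(bad, collapse = ",")))
    }
  }
  net <- rebuild_network(edges_l$geoms, ef)
  cen <- admissibility_census(net)
  if (!cen$admissible) err <- c(err, cen$problems)
  # binaryID parent/child consistency via node topology
  e <- net$edges
  prev <- prev_rids_for(e)
  for (i in seq_len(nrow(e))) {
    for (p in prev[[i]]) {
      pb <- e$binaryID[match(p, e$rid)]
      if (nchar(pb) != nchar(e$binaryID[i]) + 1L || substr(pb, 1, nchar(e$binaryID[i])) != e$binaryID[i])
        err <- c(err, sprintf("binaryID of rid %d is not its downstream edge's id plus one character", p))
    }
  }
  if (length(err)) stop(".ssn validation failed:\n  - ", paste(unique(err), collapse = "\n  - "))
  list(net = net,
       sites = if (!is.null(sites_l)) cbind(site_xy(sites_l), sites_l$fields) else NULL,
       preds = if (!is.null(preds_l)) cbind(site_xy(preds_l), preds_l$fields) else NULL)
}

site_xy <- function(l) {
  xy <- do.call(rbind, l$geoms)
  data.frame(x = xy[, 1], y = xy[, 2])
}

# Rebuild a stream_network skeleton from exported geometry + attributes.
# Nodes are matched on endpoint coordinates (1e-6 m tolerance via rounding).
rebuild_network <- function(geoms, ef) {
  key <- function(p) paste(sprintf("%.6f", p[1]), sprintf("%.6f", p[2]))
  node_ids <- new.env(parent = emptyenv())
  nodes <- list()
  get_node <- function(p) {
    k <- key(p)
    id <- node_ids[[k]]
    if (is.null(id)) {
      id <- length(nodes) + 1L
      node_ids[[k]] <- id
      nodes[[id]] <<- c(p[1], p[2])
    }
    id
  }
  m <- length(geoms)
  from_node <- to_node <- integer(m)
  for (i in seq_len(m)) {
    g <- geoms[[i]]
    from_node[i] <- get_node(g[1, ])
    to_node[i] <- get_node(g[nrow(g), ])
  }
  nd <- do.call(rbind, nodes)
  e <- data.frame(rid = as.integer(ef$rid), netID = as.integer(ef$netID),
                  from_node = from_node, to_node = to_node,
                  length_m = ef$Length, upDist_m = ef$upDist,
                  binaryID = ef$binaryID,
                  shreve = if ("shreve" %in% names(ef)) as.integer(ef$shreve) else NA_integer_,
                  rca_km2 = if ("rcaAreaKm2" %in% names(ef)) ef$rcaAreaKm2 else NA_real_,
                  h2o_km2 = if ("H2OAreaKm2" %in% names(ef)) ef$H2OAreaKm2 else NA_real_,
                  artificial = if ("rcaAreaKm2" %in% names(ef)) ef$rcaAreaKm2 == 0 else FALSE,
                  stringsAsFactors = FALSE)
  gl <- geoms
  names(gl) <- as.character(e$rid)
  inn <- table(to_node)
  kind <- rep("source", nrow(nd))
  kind[as.integer(names(inn)[inn >= 2])] <- "confluence"
  kind[setdiff(unique(to_node), from_node)] <- "outlet"
  structure(list(edges = e, geoms = gl,
                 rca = stats::setNames(vector("list", m), as.character(e$rid)),
                 cells = stats::setNames(vector("list", m), as.character(e$rid)),
                 nodes = data.frame(node_id = seq_len(nrow(nd)), x = nd[, 1], y = nd[, 2],
                                    kind = kind, stringsAsFactors = FALSE),
                 grid = list(nrows = NA_integer_, ncols = NA_integer_, cell_size = NA_real_,
                             origin_x = NA_real_, origin_y = NA_real_, crs_tag = ""),
                 attr_cols = character(0)),
            class = "stream_network")
}
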