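# Predictor summarisation: per-edge reach-contributing-area (RCA) and
# cumulative-catchment statistics, and their transfer to sites either by
# linear interpolation along the edge (approximate, cheap) or by exact
# per-site catchment delineation.

#' Define a predictor layer
#'
#' @param name column-name stem used for all derived attributes.
#' @param grid a [raster_grid()] (continuous values, or integer class codes
#'   for a categorical layer). Exactly one of `grid`/`polygons` must be
#'   given.
#' @param polygons list of polygon rings; rasterised to the DEM grid by
#'   cell-centre-in-polygon before any summarisation.
#' @param classes integer class code per polygon (categorical polygon
#'   layers).
#' @param kind `"continuous"` or `"categorical"`.
#' @param stats summary statistics to compute: any of `"mean"`, `"sum"`
#'   (continuous) and `"percent"`, `"area_km2"` (categorical).
#' @return A `predictor_layer` object.
#' @export
predictor_layer <- function(name, grid = NULL, polygons = NULL, classes = NULL,
                            kind = c("continuous", "categorical"),
                            stats = if (kind[1] == "continuous") "mean" else "percent") {
  kind <- match.arg(kind)
  if (is.null(grid) == is.null(polygons))
    stop("give exactly one of grid / polygons")
  ok <- if (kind == "continuous") c("mean", "sum") else c("percent", "area_km2")
  if (!all(stats %in% ok))
    stop(sprintf("stats for a %s layer must be in {%s}", kind, paste(ok, collapse = ", ")))
  structure(list(name = name, grid = grid, polygons = polygons, classes = classes,
                 kind = kind, stats = stats),
            class = "predictor_layer")
}

#' Rasterize polygons by cell centre
#'
#' Each grid cell takes the value of the polygon containing its centre
#' (first matching polygon wins; cells covered by no polygon get `NA`).
#'
#' @param grid template [raster_grid()].
#' @param polygons list of rings (2-column xy matrices).
#' @param values numeric value per polygon.
#' @return A [raster_grid()].
#' @export
rasterize_polygons <- function(grid, polygons, values) {
  stopifnot(length(polygons) == length(values))
  n <- grid$nrows * grid$ncols
  xy <- cell_xy(grid, seq_len(n))
  out <- rep(NA_real_, n)
  for (i in seq_along(polygons)) {
    todo <- is.na(out)
    if (!any(todo)) break
    inside <- points_in_polygon(xy[todo, 1], xy[todo, 2], polygons[[i]])
    out[which(todo)[inside]] <- values[i]
  }
  raster_grid(matrix(out, grid$nrows, grid$ncols), cell_size = grid$cell_size,
              origin_x = grid$origin_x, origin_y = grid$origin_y,
              nodata = grid$nodata, crs_tag = grid$crs_tag)
}

# Resolve a layer to a value vector over grid cells (rasterising polygons).
layer_values <- function(layer, grid_meta) {
  tmpl <- structure(grid_meta, class = "raster_grid")
  if (!is.null(layer$grid)) {
    check_same_grid(tmpl, layer$grid, sprintf("predictor layer '%s'", layer$name))
    as.numeric(layer$grid$values)
  } else {
    as.numeric(rasterize_polygons(tmpl, layer$polygons, layer$classes)$values)
  }
}

#' Summarise predictor layers over edge RCAs and catchments
#'
#' For every edge and layer, computes the summary over the edge's reach
#' contributing area (`*_rca` columns) and over the cumulative catchment of
#' the edge's downstream node (`*_cum` columns). Cumulative sums are built
#' by upstream aggregation — `cum(e) = rca(e) + sum over upstream edges` —
#' which is exact because RCA cell sets are disjoint. Means and percents are
#' derived from the aggregated sums and cell counts; nodata cells are
#' excluded from both numerator and denominator of means.
#'
#' @param net a `stream_network`.
#' @param layers list of [predictor_layer()]s.
#' @return The network with new attribute columns on `$edges` and internal
#'   per-layer sum tables used by [sites_attributes_approx()].
#' @export
attach_edge_attributes <- function(net, layers) {
  if (inherits(layers, "predictor_layer")) layers <- list(layers)
  e <- net$edges
  m <- nrow(e)
  prev <- prev_rids_for(e)
  idx_of_rid <- seq_len(m); names(idx_of_rid) <- as.character(e$rid)
  km2 <- net$grid$cell_size^2 / 1e6
  # upstream-first processing order (post-order over each in-tree)
  ord <- order(nchar_safe(e$binaryID), decreasing = TRUE)
  if (anyNA(e$binaryID)) {  # fall back to iterative relaxation order
    ord <- topo_order_upstream_first(e, prev, idx_of_rid)
  }
  net$pred_sums <- net$pred_sums %||% list()
  for (layer in layers) {
    vals <- layer_values(layer, net$grid)
    if (layer$kind == "continuous") {
      rca_sum <- rca_n <- numeric(m)
      for (i in seq_len(m)) {
        cells <- net$rca[[as.character(e$rid[i])]]
        v <- vals[cells]
        rca_sum[i] <- sum(v, na.rm = TRUE)
        rca_n[i] <- sum(!is.na(v))
      }
      cum_sum <- rca_sum; cum_n <- rca_n
      for (i in ord) {
        ps <- prev[[i]]
        if (length(ps)) {
          pidx <- idx_of_rid[as.character(ps)]
          cum_sum[i] <- rca_sum[i] + sum(cum_sum[pidx])
          cum_n[i] <- rca_n[i] + sum(cum_n[pidx])
        }
      }
      tab <- data.frame(rid = e$rid, rca_sum = rca_sum, rca_n = rca_n,
                        cum_sum = cum_sum, cum_n = cum_n)
      for (st in layer$stats) {
        if (st == "mean") {
          e[[paste0(layer$name, "_mean_rca")]] <- ifelse(rca_n > 0, rca_sum / rca_n, NA_real_)
          e[[paste0(layer$name, "_mean_cum")]] <- ifelse(cum_n > 0, cum_sum / cum_n, NA_real_)
        } else if (st == "sum") {
          e[[paste0(layer$name, "_sum_rca")]] <- rca_sum
          e[[paste0(layer$name, "_sum_cum")]] <- cum_sum
        }
      }
      net$pred_sums[[layer$name]] <- list(kind = "continuous", tab = tab, stats = layer$stats)
    } else {
      cls <- sort(unique(vals[!is.na(vals)]))
      rca_cnt <- matrix(0, m, length(cls), dimnames = list(NULL, as.character(cls)))
      rca_tot <- numeric(m)
      for (i in seq_len(m)) {
        cells <- net$rca[[as.character(e$rid[i])]]
        v <- vals[cells]
        v <- v[!is.na(v)]
        rca_tot[i] <- length(v)
        if (length(v)) {
          tb <- table(factor(v, levels = cls))
          rca_cnt[i, ] <- as.numeric(tb)
        }
      }
      cum_cnt <- rca_cnt; cum_tot <- rca_tot
      for (i in ord) {
        ps <- prev[[i]]
        if (length(ps)) {
          pidx <- idx_of_rid[as.character(ps)]
          cum_cnt[i, ] <- rca_cnt[i, ] + colSums(cum_cnt[pidx, , drop = FALSE])
          cum_tot[i] <- rca_tot[i] + sum(cum_tot[pidx])
        }
      }
      for (cl in seq_along(cls)) {
        stem <- paste0(layer$name, "_", cls[cl])
        if ("percent" %in% layer$stats) {
          e[[paste0(stem, "_pct_rca")]] <- ifelse(rca_tot > 0, 100 * rca_cnt[, cl] / rca_tot, NA_real_)
          e[[paste0(stem, "_pct_cum")]] <- ifelse(cum_tot > 0, 100 * cum_cnt[, cl] / cum_tot, NA_real_)
        }
        if ("area_km2" %in% layer$stats) {
          e[[paste0(stem, "_km2_rca")]] <- rca_cnt[, cl] * km2
          e[[paste0(stem, "_km2_cum")]] <- cum_cnt[, cl] * km2
        }
      }
      net$pred_sums[[layer$name]] <- list(kind = "categorical", classes = cls,
                                          rca_cnt = rca_cnt, cum_cnt = cum_cnt,
                                          rca_tot = rca_tot, cum_tot = cum_tot,
                                          rid = e$rid, stats = layer$stats)
    }
  }
  new_cols <- setdiff(names(e), names(net$edges))
  net$attr_cols <- union(net$attr_cols, new_cols)
  net$edges <- e
  net
}

nchar_safe <- function(x) ifelse(is.na(x), 0L, nchar(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upstream-first order by repeated relaxation (works with any in-forest).
topo_order_upstream_first <- function(e, prev, idx_of_rid) {
  m <- nrow(e)
  depth <- rep(0L, m)  # max upstream chain length
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(m)) {
      ps <- prev[[i]]
      if (length(ps)) {
        d <- max(depth[idx_of_rid[as.character(ps)]]) + 1L
        if (d > depth[i]) { depth[i] <- d; changed <- TRUE }
      }
    }
  }
  order(depth)
}

#' Approximate site attribution from edge summaries
#'
#' Transfers edge-level catchment summaries to sites by linear interpolation
#' of the edge's RCA along the segment: for any additive quantity,
#' `approx_cum(site) = cum(edge) - ratio * rca(edge)`, with `ratio` measured
#' from the edge's downstream junction. At `ratio = 0` this reproduces the
#' downstream-node catchment summary; at `ratio = 1` it equals the sum over
#' the upstream edges. Means and percents are recomputed from the
#' interpolated sums and the interpolated cell count. Output columns carry
#' the suffix `_avg`; the approximate catchment area is `H2OArea_avg` (km2).
#'
#' @param sites data.frame from [snap_sites()] or
#'   [generate_prediction_sites()].
#' @param net a `stream_network` with [attach_edge_attributes()] already
#'   applied.
#' @param layers the same [predictor_layer()] list used on the edges.
#' @return `sites` with appended attribute columns.
#' @export
sites_attributes_approx <- function(sites, net, layers) {
  if (inherits(layers, "predictor_layer")) layers <- list(layers)
  if (is.null(net$pred_sums)) stop("run attach_edge_attributes() first")
  e <- net$edges
  ei <- match(sites$rid, e$rid)
  if (anyNA(ei)) stop("site references a rid that is not in the network")
  ratio <- sites$ratio
  sites$H2OArea_avg <- e$h2o_km2[ei] - ratio * e$rca_km2[ei]
  for (layer in layers) {
    ps <- net$pred_sums[[layer$name]]
    if (is.null(ps)) stop("no edge summaries for layer ", layer$name)
    if (ps$kind == "continuous") {
      ti <- match(sites$rid, ps$tab$rid)
      s_sum <- ps$tab$cum_sum[ti] - ratio * ps$tab$rca_sum[ti]
      s_n <- ps$tab$cum_n[ti] - ratio * ps$tab$rca_n[ti]
      for (st in layer$stats) {
        if (st == "mean") sites[[paste0(layer$name, "_mean_avg")]] <- ifelse(s_n > 0, s_sum / s_n, NA_real_)
        if (st == "sum") sites[[paste0(layer$name, "_sum_avg")]] <- s_sum
      }
    } else {
      ti <- match(sites$rid, ps$rid)
      tot <- ps$cum_tot[ti] - ratio * ps$rca_tot[ti]
      km2 <- net$grid$cell_size^2 / 1e6
      for (cl in seq_along(ps$classes)) {
        cnt <- ps$cum_cnt[ti, cl] - ratio * ps$rca_cnt[ti, cl]
        stem <- paste0(layer$name, "_", ps$classes[cl])
        if ("percent" %in% layer$stats)
          sites[[paste0(stem, "_pct_avg")]] <- ifelse(tot > 0, 100 * cnt / tot, NA_real_)
        if ("area_km2" %in% layer$stats)
          sites[[paste0(stem, "_km2_avg")]] <- cnt * km2
      }
    }
  }
  sites
}

#' Exact site attribution from per-site catchments
#'
#' Delineates the exact D8 catchment of every site and summarises the
#' layers directly over that cell set. The catchment seed is the stream cell
#' of the site's edge containing (or nearest to) the snapped point; seeding
#' on the edge's own stream path keeps the site catchment nested inside the
#' edge catchment, so `|approx - exact| <= rca(edge)` holds for every
#' additive quantity. Output columns carry the suffix `_exact`; the exact
#' catchment area is `H2OArea_exact` (km2).
#'
#' @param sites snapped sites.
#' @param fd the `flow_dir` the network was derived on.
#' @param layers list of [predictor_layer()]s.
#' @param dem the DEM grid (for co-registration checks).
#' @param net the `stream_network` (supplies each edge's stream-cell path).
#' @return `sites` with appended attribute columns.
#' @export
sites_attributes_exact <- function(sites, fd, layers, dem, net) {
  if (inherits(layers, "predictor_layer")) layers <- list(layers)
  grid_meta <- net$grid
  tmpl <- structure(grid_meta, class = "raster_grid")
  vals <- lapply(layers, layer_values, grid_meta = grid_meta)
  km2 <- grid_meta$cell_size^2 / 1e6
  n_sites <- nrow(sites)
  sites$H2OArea_exact <- NA_real_
  for (i in seq_len(n_sites)) {
    cells_e <- net$cells[[as.character(sites$rid[i])]]
    seed <- xy_cell(tmpl, sites$x[i], sites$y[i])
    if (!length(cells_e)) {
      warning(sprintf("site %d sits on an artificial edge; using its raw cell", i))
    } else if (is.na(seed) || !(seed %in% cells_e)) {
      if (!is.na(seed) && !(seed %in% cells_e))
        seed <- nearest_cell(tmpl, cells_e, sites$x[i], sites$y[i])
      else if (is.na(seed))
        stop(sprintf("site %d lies off the grid", i))
    }
    catch <- upstream_cells(fd, seed)
    sites$H2OArea_exact[i] <- length(catch) * km2
    for (li in seq_along(layers)) {
      layer <- layers[[li]]
      v <- vals[[li]][catch]
      v <- v[!is.na(v)]
      if (layer$kind == "continuous") {
        for (st in layer$stats) {
          col <- paste0(layer$name, "_", st, "_exact")
          if (!col %in% names(sites)) sites[[col]] <- NA_real_
          sites[[col]][i] <- if (st == "mean") mean(v) else sum(v)
        }
      } else {
        ps <- net$pred_sums[[layer$name]]
        cls <- if (!is.null(ps)) ps$classes else sort(unique(vals[[li]][!is.na(vals[[li]])]))
        tb <- table(factor(v, levels = cls))
        for (cl in seq_along(cls)) {
          stem <- paste0(layer$name, "_", cls[cl])
          if ("percent" %in% layer$stats) {
            col <- paste0(stem, "_pct_exact")
            if (!col %in% names(sites)) sites[[col]] <- NA_real_
            sites[[col]][i] <- if (length(v)) 100 * as.numeric(tb[cl]) / length(v) else NA_real_
          }
          if ("area_km2" %in% layer$stats) {
            col <- paste0(stem, "_km2_exact")
            if (!col %in% names(sites)) sites[[col]] <- NA_real_
            sites[[col]][i] <- as.numeric(tb[cl]) * km2
          }
        }
      }
    }
  }
  sites
}

nearest_cell <- function(tmpl, cells, x, y) {
  xy <- cell_xy(tmpl, cells)
  d2 <- (xy[, 1] - x)^2 + (xy[, 2] - y)^2
  cells[which.min(d2)]
}
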