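# One-shot pipeline driver and a small command-line front end.

#' Run the full preprocessing pipeline from a configuration
#'
#' Executes DEM conditioning (optional burn-in, depression filling), flow
#' routing, stream extraction, topology correction, optional lake severing,
#' site snapping, optional prediction-site generation, predictor
#' attribution and `.ssn` export, logging counts of every dropped, moved or
#' corrected entity.
#'
#' @param config a list or path to a JSON file with entries:
#'   `dem` (path to an ASCII grid) or `fixture` (a [fixture_spec()] list);
#'   `sites` (path to a GeoJSON point layer; defaults to fixture sites);
#'   `accum_threshold`, `min_stream_length`, `routing` ("mfd"/"d8"),
#'   `burn_streams` (path) + `burn_depth` (m), `lakes` (path),
#'   `max_snap_dist` (m), `pred_n_sites` or `pred_spacing_m`,
#'   `predictors` (list of: name, path or fixture_landuse = TRUE, kind,
#'   stats), `measurements` (CSV path) + `site_key`, `attribution`
#'   ("approx"/"exact"/"both"), `out` (.ssn directory), `overwrite`.
#' @return The [export_ssn()] dataset handle, invisibly; the intermediate
#'   objects are attached as attributes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- config
  get_or <- function(nm, default) if (!is.null(cfg[[nm]])) cfg[[nm]] else default
  fixture <- NULL
  if (!is.null(cfg$fixture)) {
    fixture <- do.call(fixture_spec, cfg$fixture)
    dem <- make_dem(fixture)
  } else if (!is.null(cfg$dem)) {
    dem <- read_raster(cfg$dem)
  } else stop("config needs 'dem' or 'fixture'")
  if (!is.null(cfg$burn_streams)) {
    burn <- read_geojson(cfg$burn_streams)
    if (is.null(cfg$burn_depth)) stop("burn_streams given without burn_depth")
    dem <- burn_streams(dem, burn, cfg$burn_depth)
    message(sprintf("burned %d line feature(s) by %g m", length(burn$geoms), cfg$burn_depth))
  }
  demf <- fill_depressions(dem)
  routing <- match.arg(get_or("routing", "mfd"), c("mfd", "d8"))
  fd <- if (routing == "mfd") mfd_directions(demf) else d8_directions(demf)
  acc <- accumulate(fd, routing)
  streams <- extract_streams(acc, fd, get_or("accum_threshold", 20),
                             get_or("min_stream_length", 10))
  net <- vectorize(streams, fd, demf)
  cx <- check_complex_confluences(net)
  if (length(cx)) {
    message(sprintf("correcting %d complex confluence(s)", length(cx)))
    net <- correct_complex_confluences(net, get_or("confluence_offset_fraction", 0.25))
  }
  if (!is.null(cfg$lakes)) net <- delete_lakes(net, read_geojson(cfg$lakes))
  layers <- list()
  preds_cfg <- get_or("predictors", list())
  if (is.data.frame(preds_cfg))   # read_json(simplifyVector = TRUE) form
    preds_cfg <- lapply(seq_len(nrow(preds_cfg)), function(i) as.list(preds_cfg[i, ]))
  for (p in preds_cfg) {
    if (isTRUE(p$fixture_landuse)) {
      if (is.null(fixture)) stop("fixture_landuse predictor requires a fixture config")
      lu <- make_landuse(fixture, demf)
      layers[[length(layers) + 1L]] <- predictor_layer(p$name, grid = lu$raster,
                                                       kind = "categorical",
                                                       stats = p$stats %||% "percent")
    } else {
      layers[[length(layers) + 1L]] <- predictor_layer(p$name, grid = read_raster(p$path),
                                                       kind = p$kind %||% "continuous",
                                                       stats = p$stats %||% "mean")
    }
  }
  if (length(layers)) net <- attach_edge_attributes(net, layers)
  if (!is.null(cfg$sites)) {
    pts <- read_geojson(cfg$sites)
  } else if (!is.null(fixture)) {
    pts <- make_sites(fixture, net)
  } else stop("config needs 'sites' (or a fixture)")
  sn <- snap_sites(pts, net, get_or("max_snap_dist", 150))
  sites <- sn$sites
  message(sprintf("snapped %d site(s), dropped %d, median snap distance %.1f m",
                  nrow(sites), length(sn$dropped), stats::median(sites$dist_moved)))
  attribution <- get_or("attribution", "approx")
  if (length(layers)) {
    if (attribution %in% c("approx", "both"))
      sites <- sites_attributes_approx(sites, net, layers)
    if (attribution %in% c("exact", "both"))
      sites <- sites_attributes_exact(sites, fd, layers, demf, net)
  }
  if (!is.null(cfg$measurements)) {
    meas <- utils::read.csv(cfg$measurements)
    sites <- merge_sites_with_measurements(sites, meas, get_or("site_key", "locID"))
    message(sprintf("expanded to %d measurement record(s)", nrow(sites)))
  }
  preds <- NULL
  if (!is.null(cfg$pred_n_sites) || !is.null(cfg$pred_spacing_m)) {
    preds <- generate_prediction_sites(net, n_sites = cfg$pred_n_sites,
                                       spacing_m = cfg$pred_spacing_m)
    if (length(layers)) preds <- sites_attributes_approx(preds, net, layers)
    message(sprintf("generated %d prediction site(s)", nrow(preds)))
  }
  out <- get_or("out", "streamprep_out.ssn")
  ds <- export_ssn(net, sites, preds, out, overwrite = isTRUE(cfg$overwrite),
                   net_file_style = get_or("net_file_style", "netID"),
                   layer_format = get_or("layer_format", "shapefile"))
  message("exported .ssn dataset to ", out)
  attr(ds, "net") <- net
  attr(ds, "sites") <- sites
  attr(ds, "preds") <- preds
  attr(ds, "flow_dir") <- fd
  invisible(ds)
}

#' Command-line entry point
#'
#' `streamprep run --config cfg.json` runs the pipeline;
#' `streamprep fixtures --spec spec.json --out dir/` writes synthetic inputs
#' (DEM as ASCII grid, sites as GeoJSON, land use as ASCII grid + GeoJSON
#' polygons) that the main pipeline can read back.
#'
#' @param args character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly.
#' @export
streamprep_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: streamprep <run|fixtures> [--config f.json | --spec f.json --out dir] [--overwrite]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else NULL
  }
  if (cmd == "run") {
    cfgf <- opt("--config")
    if (is.null(cfgf)) stop("run needs --config <file.json>")
    cfg <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
    if ("--overwrite" %in% args) cfg$overwrite <- TRUE
    run_pipeline(cfg)
    return(invisible(0L))
  }
  if (cmd == "fixtures") {
    specf <- opt("--spec"); outd <- opt("--out")
    if (is.null(outd)) stop("fixtures needs --out <dir>")
    spec <- if (!is.null(specf))
      do.call(fixture_spec, jsonlite::read_json(specf, simplifyVector = TRUE))
    else fixture_spec()
    dir.create(outd, showWarnings = FALSE, recursive = TRUE)
    dem <- make_dem(spec)
    write_ascii_grid(dem, file.path(outd, "dem.asc"))
    demf <- fill_depressions(dem)
    fd <- mfd_directions(demf)
    net <- vectorize(extract_streams(accumulate(fd, "mfd"), fd, 20, 15), fd, demf)
    net <- correct_complex_confluences(net)
    pts <- make_sites(spec, net)
    write_geojson(lapply(seq_len(nrow(pts)), function(i) cbind(pts$x[i], pts$y[i])),
                  "Point", file.path(outd, "sites.geojson"),
                  properties = pts[c("site_id", "true_rid", "true_ratio")])
    lu <- make_landuse(spec, dem)
    write_ascii_grid(lu$raster, file.path(outd, "landuse.asc"))
    write_geojson(lu$polygons, "Polygon", file.path(outd, "landuse.geojson"),
                  properties = data.frame(class = lu$classes))
    jsonlite::write_json(unclass(spec), file.path(outd, "fixture_spec.json"), auto_unbox = TRUE)
    message("fixtures written to ", outd)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
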