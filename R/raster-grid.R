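#' Georeferenced raster grid
#'
#' The basic cell matrix underlying all flow computations: a numeric matrix
#' with square cells, row 1 being the northernmost row. Nodata cells are held
#' as `NA` internally; `nodata` records the sentinel used on disk.
#'
#' The origin (`origin_x`, `origin_y`) is the *outer* (north-west) corner of
#' cell (1, 1); the centre of cell (r, c) is at
#' `(origin_x + (c - 0.5) * cell_size, origin_y - (r - 0.5) * cell_size)`.
#'
#' @param values numeric matrix (rows = north to south).
#' @param cell_size cell edge length in map units (metres), `> 0`.
#' @param origin_x,origin_y map coordinates of the north-west grid corner.
#' @param nodata sentinel value used when reading/writing files.
#' @param crs_tag opaque CRS string (e.g. a PROJ or WKT string); carried
#'   through unchanged and written to `.prj` sidecars.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin_x = 0, origin_y = nrow(values) * cell_size,
                        nodata = -9999, crs_tag = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a single positive number")
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, nrows = nrow(values), ncols = ncol(values),
         cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         nodata = nodata, crs_tag = crs_tag),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, cell_size %g m\n", x$nrows, x$ncols, x$cell_size))
  cat(sprintf("  origin (NW corner): %g, %g; nodata cells: %d\n",
              x$origin_x, x$origin_y, sum(is.na(x$values))))
  invisible(x)
}

# ---- cell index helpers (column-major single index, as R stores matrices) ----

cell_index <- function(grid, row, col) (col - 1L) * grid$nrows + row

cell_rowcol <- function(grid, idx) {
  idx <- as.integer(idx)
  col <- (idx - 1L) %/% grid$nrows + 1L
  row <- idx - (col - 1L) * grid$nrows
  cbind(row = row, col = col)
}

#' Map coordinates of cell centres
#' @param grid a [raster_grid()].
#' @param idx integer cell indices (column-major).
#' @return two-column matrix of x/y centre coordinates.
#' @keywords internal
cell_xy <- function(grid, idx) {
  rc <- cell_rowcol(grid, idx)
  cbind(x = grid$origin_x + (rc[, "col"] - 0.5) * grid$cell_size,
        y = grid$origin_y - (rc[, "row"] - 0.5) * grid$cell_size)
}

# Cell containing a map coordinate; NA if off grid.
xy_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  bad <- col < 1 | col > grid$ncols | row < 1 | row > grid$nrows |
    !is.finite(col) | !is.finite(row)
  out <- cell_index(grid, as.integer(row), as.integer(col))
  out[bad] <- NA_integer_
  out
}

# All grids in one run must be co-registered.
check_same_grid <- function(a, b, what = "grid") {
  ok <- a$nrows == b$nrows && a$ncols == b$ncols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
  if (!ok) stop(sprintf("%s is not co-registered with the DEM (dims/cell_size/origin differ)", what))
  invisible(TRUE)
}

# ---- file I/O -----------------------------------------------------------

#' Read a single-band raster
#'
#' Reads an ESRI ASCII grid (`.asc`/`.agr`/`.txt`, the standard text raster
#' interchange format). A sidecar `.prj` file next to the raster, if present,
#' supplies `crs_tag`. GeoTIFF is not supported in this build; convert with
#' e.g. `gdal_translate -of AAIGrid` beforehand.
#'
#' @param path path to the raster file.
#' @return A [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  head4 <- readBin(path, "raw", n = 4L)
  if (length(head4) >= 4L &&
      (identical(head4[1:2], as.raw(c(0x49, 0x49))) || identical(head4[1:2], as.raw(c(0x4d, 0x4d)))))
    stop("GeoTIFF input is not supported; convert to ESRI ASCII grid first")
  read_ascii_grid(path)
}

#' @rdname read_raster
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1]) && !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not a valid ESRI ASCII grid (missing ", paste(setdiff(need, names(hdr)), collapse = ", "), "): ", path)
  if (!is.null(hdr$dx) || !is.null(hdr$dy))
    stop("non-square cells (dx/dy header) are not supported")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid has %d values, expected %d (%d x %d)", length(vals), nr * nc, nr, nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # file order is row-major, north first
  if (!is.null(hdr$xllcenter)) {
    ox <- hdr$xllcenter - hdr$cellsize / 2
    oy <- hdr$yllcenter - hdr$cellsize / 2 + nr * hdr$cellsize
  } else {
    ox <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
    oy <- (if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0) + nr * hdr$cellsize
  }
  crs <- ""
  prj <- sub("\\.[^.]+$", ".prj", path)
  if (prj != path && file.exists(prj)) crs <- paste(readLines(prj, warn = FALSE), collapse = "\n")
  raster_grid(m, cell_size = hdr$cellsize, origin_x = ox, origin_y = oy,
              nodata = nodata, crs_tag = crs)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param grid a [raster_grid()].
#' @param path output path; a `.prj` sidecar is written when `crs_tag` is set.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "raster_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y - grid$nrows * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  for (r in seq_len(grid$nrows))
    writeLines(paste(formatC(v[r, ], format = "g", digits = digits), collapse = " "), con)
  if (nzchar(grid$crs_tag))
    writeLines(grid$crs_tag, sub("\\.[^.]+$", ".prj", path))
  invisible(path)
}
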