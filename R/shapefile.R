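# Minimal ESRI Shapefile I/O: Point (type 1) and PolyLine (type 3) layers
# with DBF attribute tables. Implemented in-package because the .ssn
# consumers expect shapefile layers and no pre-installed package provides a
# driver. Only the subset needed for .ssn datasets is supported: 2D
# single-part geometries, C (character) and N (numeric) DBF fields.

shp_write_header <- function(con, shape_type, file_words, bbox) {
  writeBin(9994L, con, size = 4, endian = "big")
  writeBin(rep(0L, 5), con, size = 4, endian = "big")
  writeBin(as.integer(file_words), con, size = 4, endian = "big")
  writeBin(1000L, con, size = 4, endian = "little")
  writeBin(as.integer(shape_type), con, size = 4, endian = "little")
  writeBin(as.numeric(bbox), con, size = 8, endian = "little")  # xmin ymin xmax ymax
  writeBin(rep(0, 4), con, size = 8, endian = "little")          # z/m ranges
}

#' Write a shapefile layer
#'
#' @param geoms list of 2-column xy matrices: 1-row matrices for a point
#'   layer, polylines otherwise (all features must be the same type).
#' @param fields data.frame of attributes (numeric or character columns),
#'   one row per feature.
#' @param path output path without extension; writes `.shp`, `.shx`, `.dbf`
#'   and, when `crs_tag` is non-empty, `.prj`.
#' @param point `TRUE` for a point layer.
#' @param crs_tag CRS text for the `.prj` sidecar.
#' @return `path`, invisibly.
#' @keywords internal
write_shapefile <- function(geoms, fields, path, point = FALSE, crs_tag = "") {
  n <- length(geoms)
  stopifnot(n == nrow(fields))
  allxy <- do.call(rbind, geoms)
  bbox <- c(min(allxy[, 1]), min(allxy[, 2]), max(allxy[, 1]), max(allxy[, 2]))
  shape_type <- if (point) 1L else 3L
  # record content lengths in 16-bit words
  # content bytes: type(4) + bbox(32) + counts(8) + parts(4) + points(16 n)
  rec_words <- vapply(geoms, function(g) {
    if (point) 10L else as.integer((4L + 32L + 8L + 4L + 16L * nrow(g)) / 2L)
  }, integer(1))
  file_words <- 50L + sum(rec_words + 4L)
  con <- file(paste0(path, ".shp"), "wb")
  shp_write_header(con, shape_type, file_words, bbox)
  offsets <- integer(n)
  off <- 50L
  for (i in seq_len(n)) {
    g <- geoms[[i]]
    offsets[i] <- off
    writeBin(i, con, size = 4, endian = "big")
    writeBin(rec_words[i], con, size = 4, endian = "big")
    writeBin(shape_type, con, size = 4, endian = "little")
    if (point) {
      writeBin(as.numeric(g[1, 1:2]), con, size = 8, endian = "little")
    } else {
      writeBin(c(min(g[, 1]), min(g[, 2]), max(g[, 1]), max(g[, 2])), con, size = 8, endian = "little")
      writeBin(c(1L, nrow(g)), con, size = 4, endian = "little")  # numParts, numPoints
      writeBin(0L, con, size = 4, endian = "little")              # part start
      writeBin(as.numeric(t(g)), con, size = 8, endian = "little")
    }
    off <- off + 4L + rec_words[i]
  }
  close(con)
  con <- file(paste0(path, ".shx"), "wb")
  shp_write_header(con, shape_type, 50L + 4L * n, bbox)
  for (i in seq_len(n)) {
    writeBin(offsets[i], con, size = 4, endian = "big")
    writeBin(rec_words[i], con, size = 4, endian = "big")
  }
  close(con)
  write_dbf(fields, paste0(path, ".dbf"))
  if (nzchar(crs_tag)) writeLines(crs_tag, paste0(path, ".prj"))
  invisible(path)
}

# DBF numeric formatting: integers as integers, doubles with 8 decimals.
dbf_field_spec <- function(col) {
  if (is.numeric(col)) {
    if (all(is.finite(col)) && all(col == round(col)) && max(abs(col), 0) < 2^31)
      list(type = "N", width = 10L, dec = 0L)
    else list(type = "N", width = 19L, dec = 8L)
  } else {
    w <- max(nchar(as.character(col), type = "bytes"), 1L)
    list(type = "C", width = as.integer(min(max(w, 10L), 254L)), dec = 0L)
  }
}

write_dbf <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  specs <- lapply(df, dbf_field_spec)
  nms <- substr(names(df), 1, 10)
  if (anyDuplicated(nms)) stop("duplicate DBF field names after truncation: use abbrev_fields()")
  nrec <- nrow(df)
  recsize <- 1L + sum(vapply(specs, function(s) s$width, integer(1)))
  hdrsize <- 32L + 32L * length(specs) + 1L
  con <- file(path, "wb")
  writeBin(as.raw(c(0x03, 95, 1, 1)), con)  # version, fixed fake date (determinism)
  writeBin(as.integer(nrec), con, size = 4, endian = "little")
  writeBin(as.integer(hdrsize), con, size = 2, endian = "little")
  writeBin(as.integer(recsize), con, size = 2, endian = "little")
  writeBin(raw(20), con)
  for (i in seq_along(specs)) {
    nm <- charToRaw(nms[i])
    writeBin(c(nm, raw(11 - length(nm))), con)
    writeBin(charToRaw(specs[[i]]$type), con)
    writeBin(raw(4), con)
    writeBin(as.raw(specs[[i]]$width), con)
    writeBin(as.raw(specs[[i]]$dec), con)
    writeBin(raw(14), con)
  }
  writeBin(as.raw(0x0D), con)
  for (r in seq_len(nrec)) {
    rec <- " "
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      v <- df[[i]][r]
      txt <- if (s$type == "N") {
        if (is.na(v)) strrep(" ", s$width)
        else formatC(as.numeric(v), format = if (s$dec > 0) "f" else "d",
                     digits = if (s$dec > 0) s$dec else NULL, width = s$width)
      } else {
        v <- if (is.na(v)) "" else as.character(v)
        formatC(v, width = -s$width)  # left-justified
      }
      if (nchar(txt, type = "bytes") > s$width) txt <- substr(txt, 1, s$width)
      rec <- paste0(rec, txt)
    }
    writeBin(charToRaw(rec), con)
  }
  writeBin(as.raw(0x1A), con)
  close(con)
  invisible(path)
}

#' Read a shapefile layer
#'
#' @param path path without extension (or with `.shp`).
#' @return list with `geoms` (list of xy matrices), `point` (logical) and
#'   `fields` (data.frame).
#' @keywords internal
read_shapefile <- function(path) {
  path <- sub("\\.shp$", "", path)
  shp <- paste0(path, ".shp")
  if (!file.exists(shp)) stop("missing shapefile: ", shp)
  raw <- readBin(shp, "raw", n = file.info(shp)$size)
  code <- readBin(raw[1:4], "integer", size = 4, endian = "big")
  if (code != 9994L) stop("not a shapefile: ", shp)
  shape_type <- readBin(raw[33:36], "integer", size = 4, endian = "little")
  if (!shape_type %in% c(1L, 3L)) stop("unsupported shape type ", shape_type)
  pos <- 101L  # 1-based byte position after 100-byte header
  geoms <- list()
  total <- length(raw)
  while (pos + 8L <= total + 1L) {
    rec_words <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4, endian = "big")
    cpos <- pos + 8L
    st <- readBin(raw[cpos:(cpos + 3L)], "integer", size = 4, endian = "little")
    if (st == 1L) {
      xy <- readBin(raw[(cpos + 4L):(cpos + 19L)], "numeric", n = 2, size = 8, endian = "little")
      geoms[[length(geoms) + 1L]] <- matrix(xy, ncol = 2)
    } else if (st == 3L) {
      np_off <- cpos + 4L + 32L
      counts <- readBin(raw[np_off:(np_off + 7L)], "integer", n = 2, size = 4, endian = "little")
      n_parts <- counts[1]; n_pts <- counts[2]
      pts_off <- np_off + 8L + 4L * n_parts
      xy <- readBin(raw[pts_off:(pts_off + 16L * n_pts - 1L)], "numeric",
                    n = 2L * n_pts, size = 8, endian = "little")
      geoms[[length(geoms) + 1L]] <- matrix(xy, ncol = 2, byrow = TRUE)
    } else stop("unsupported record shape type ", st)
    pos <- cpos + 2L * rec_words
  }
  fields <- read_dbf(paste0(path, ".dbf"))
  list(geoms = geoms, point = shape_type == 1L, fields = fields)
}

read_dbf <- function(path) {
  if (!file.exists(path)) stop("missing DBF: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  nrec <- readBin(raw[5:8], "integer", size = 4, endian = "little")
  hdrsize <- readBin(raw[9:10], "integer", size = 2, endian = "little", signed = FALSE)
  recsize <- readBin(raw[11:12], "integer", size = 2, endian = "little", signed = FALSE)
  nfields <- (hdrsize - 33L) %/% 32L
  names <- character(nfields); types <- character(nfields)
  widths <- integer(nfields); decs <- integer(nfields)
  for (i in seq_len(nfields)) {
    off <- 32L + (i - 1L) * 32L
    nm <- raw[(off + 1L):(off + 11L)]
    nm <- nm[nm != as.raw(0)]
    names[i] <- rawToChar(nm)
    types[i] <- rawToChar(raw[off + 12L])
    widths[i] <- as.integer(raw[off + 17L])
    decs[i] <- as.integer(raw[off + 18L])
  }
  out <- vector("list", nfields); names(out) <- names
  for (i in seq_len(nfields)) out[[i]] <- if (types[i] == "N") numeric(nrec) else character(nrec)
  for (r in seq_len(nrec)) {
    roff <- hdrsize + (r - 1L) * recsize + 1L  # skip deletion flag
    cpos <- roff + 1L
    for (i in seq_len(nfields)) {
      txt <- rawToChar(raw[cpos:(cpos + widths[i] - 1L)])
      if (types[i] == "N") {
        v <- suppressWarnings(as.numeric(trimws(txt)))
        out[[i]][r] <- if (length(v)) v else NA_real_
      } else {
        out[[i]][r] <- sub(" +$", "", txt)
      }
      cpos <- cpos + widths[i]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Deterministic 10-character field-name abbreviation
#'
#' Shapefile DBF field names are limited to 10 bytes. Names are truncated to
#' 10 characters; collisions are resolved by replacing the tail with a
#' 2-digit counter. The original-to-abbreviated map is returned so callers
#' can emit it as a sidecar.
#'
#' @param nms character vector of column names.
#' @return named character vector: `names()` are the originals, values the
#'   abbreviations.
#' @export
abbrev_fields <- function(nms) {
  out <- substr(nms, 1, 10)
  k <- 0L
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out) | duplicated(out, fromLast = TRUE))
    for (i in dup) {
      k <- k + 1L
      out[i] <- paste0(substr(nms[i], 1, 8), sprintf("%02d", k))
    }
  }
  stats::setNames(out, nms)
}
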