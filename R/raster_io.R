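#' Read and write single-band rasters
#'
#' Two plain single-band formats are supported: the ESRI ASCII grid
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header)
#' and an uncompressed single-band GeoTIFF (little-endian, float64 for
#' fractional values, int32 for integral rasters, with ModelPixelScale,
#' ModelTiepoint and GDAL_NODATA tags). No installed package reads
#' georeferenced TIFFs with unbounded values, so the GeoTIFF codec here is a
#' purpose-built minimal implementation of the baseline TIFF 6.0 layout.
#'
#' Round-trips are lossless for integer rasters in both formats; ASCII grids
#' store fractional values at 15 significant digits.
#'
#' @param path file path.
#' @param format `"auto"` (from the extension: `.asc`/`.txt` vs
#'   `.tif`/`.tiff`), `"ascii"` or `"geotiff"`.
#' @param crs_tag CRS identifier attached to rasters read from ASCII grids
#'   (the format itself carries none).
#' @return `read_raster` returns a [grid_raster]; `write_raster` returns the
#'   path invisibly.
#' @export
read_raster <- function(path, format = "auto", crs_tag = "local") {
  format <- resolve_format(path, format)
  if (format == "ascii") read_ascii_grid(path, crs_tag)
  else read_geotiff(path)
}

#' @rdname read_raster
#' @param raster a [grid_raster].
#' @export
write_raster <- function(raster, path, format = "auto") {
  if (!is_grid_raster(raster)) stop("`raster` must be a grid_raster")
  format <- resolve_format(path, format)
  if (format == "ascii") write_ascii_grid(raster, path)
  else write_geotiff(raster, path)
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, asc = , txt = "ascii", tif = , tiff = "geotiff",
                     stop("unknown raster format for extension '.", ext, "'"))
  }
  if (!format %in% c("ascii", "geotiff")) {
    stop("unknown format '", format, "' (use 'ascii' or 'geotiff')")
  }
  format
}

# ---- ESRI ASCII grid ----

format_cell <- function(v) {
  out <- character(length(v))
  int <- !is.na(v) & v == round(v) & abs(v) < 2^53
  out[int] <- formatC(v[int], format = "d")
  out[!int & !is.na(v)] <- formatC(v[!int & !is.na(v)], format = "g", digits = 15)
  out
}

write_ascii_grid <- function(raster, path) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- raster$origin[2] - nr * raster$cell_size
  hdr <- c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", formatC(raster$origin[1], format = "g", digits = 15)),
    paste("yllcorner", formatC(yll, format = "g", digits = 15)),
    paste("cellsize", formatC(raster$cell_size, format = "g", digits = 15)),
    paste("NODATA_value", format_cell(raster$nodata))
  )
  v[is.na(v)] <- raster$nodata
  body <- vapply(seq_len(nr), function(r) paste(format_cell(v[r, ]), collapse = " "),
                 character(1))
  writeLines(c(hdr, body), path)
}

read_ascii_grid <- function(path, crs_tag = "local") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("parse error in '", path, "': fewer than 6 lines")
  hdr <- list()
  i <- 1
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")) {
      val <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(val)) stop("parse error at line ", i, " of '", path,
                           "': non-numeric value for ", parts[1])
      hdr[[tolower(parts[1])]] <- val
      i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("parse error in '", path, "': missing header field(s) ",
                         paste(miss, collapse = ", "))
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- suppressWarnings(as.numeric(scan(text = paste(lines[i:length(lines)],
                                                        collapse = "\n"),
                                           what = character(), quiet = TRUE)))
  if (anyNA(vals)) {
    stop("parse error in '", path, "': non-numeric cell value at offset ",
         which(is.na(vals))[1])
  }
  if (length(vals) != nr * nc) {
    stop("parse error in '", path, "': expected ", nr * nc, " cells, found ",
         length(vals))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  grid_raster(m, hdr$cellsize, origin, crs_tag, nodata)
}

# ---- minimal single-band GeoTIFF ----

TIFF_TYPE_SIZE <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `12` = 8) # BYTE ASCII SHORT LONG DOUBLE

tif_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
tif_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
tif_dbl <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

write_geotiff <- function(raster, path) {
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  integral <- all(is.na(v) | (v == round(v) & abs(v) < 2^31)) &&
    raster$nodata == round(raster$nodata) && abs(raster$nodata) < 2^31
  v[is.na(v)] <- raster$nodata
  pix <- as.vector(t(v)) # row-major, top row first
  if (integral) {
    sample_format <- 2L; bits <- 32L
    pix_raw <- writeBin(as.integer(pix), raw(), size = 4, endian = "little")
  } else {
    sample_format <- 3L; bits <- 64L
    pix_raw <- writeBin(as.numeric(pix), raw(), size = 8, endian = "little")
  }
  scale <- tif_dbl(c(raster$cell_size, raster$cell_size, 0))
  tiept <- tif_dbl(c(0, 0, 0, raster$origin[1], raster$origin[2], 0))
  crs_str <- c(charToRaw(raster$crs_tag), as.raw(0))
  nod_str <- c(charToRaw(format_cell(raster$nodata)), as.raw(0))

  entries <- list( # tag, type, count, value (inline number or raw payload ref)
    list(256, 4, 1, nc), list(257, 4, 1, nr), list(258, 3, 1, bits),
    list(259, 3, 1, 1), list(262, 3, 1, 1),
    list(273, 4, 1, "STRIP"), list(277, 3, 1, 1), list(278, 4, 1, nr),
    list(279, 4, 1, length(pix_raw)), list(339, 3, 1, sample_format),
    list(33550, 12, 3, "SCALE"), list(33922, 12, 6, "TIEPT"),
    list(34737, 2, length(crs_str), "CRS"), list(42113, 2, length(nod_str), "NODATA")
  )
  n_ent <- length(entries)
  ifd_off <- 8
  data_off <- ifd_off + 2 + n_ent * 12 + 4   # out-of-line values start here
  payloads <- list(SCALE = scale, TIEPT = tiept, CRS = crs_str, NODATA = nod_str)
  offs <- list(); cur <- data_off
  for (nm in names(payloads)) {
    len <- length(payloads[[nm]])
    if (len > 4) { offs[[nm]] <- cur; cur <- cur + len + (len %% 2) }
  }
  strip_off <- cur

  ifd <- tif_u16(n_ent)
  for (e in entries) {
    ifd <- c(ifd, tif_u16(e[[1]]), tif_u16(e[[2]]), tif_u32(e[[3]]))
    val <- e[[4]]
    if (is.character(val)) {
      if (val == "STRIP") {
        ifd <- c(ifd, tif_u32(strip_off))
      } else {
        pl <- payloads[[val]]
        if (length(pl) > 4) ifd <- c(ifd, tif_u32(offs[[val]]))
        else ifd <- c(ifd, pl, raw(4 - length(pl)))
      }
    } else if (e[[2]] == 3) {
      ifd <- c(ifd, tif_u16(val), as.raw(c(0, 0)))
    } else {
      ifd <- c(ifd, tif_u32(val))
    }
  }
  ifd <- c(ifd, tif_u32(0)) # no next IFD

  out <- c(charToRaw("II"), tif_u16(42), tif_u32(ifd_off), ifd)
  for (nm in names(payloads)) {
    pl <- payloads[[nm]]
    if (length(pl) > 4) out <- c(out, pl, raw(length(pl) %% 2))
  }
  out <- c(out, pix_raw)
  writeBin(out, path)
}

read_geotiff <- function(path) {
  b <- readBin(path, raw(), n = file.info(path)$size)
  if (length(b) < 8) stop("parse error in '", path, "': truncated TIFF")
  if (rawToChar(b[1:2]) != "II") stop("unsupported TIFF byte order in '", path, "'")
  u16 <- function(off) readBin(b[(off + 1):(off + 2)], "integer", size = 2,
                               endian = "little", signed = FALSE)
  u32 <- function(off) readBin(b[(off + 1):(off + 4)], "integer", size = 4,
                               endian = "little")
  if (u16(2) != 42) stop("parse error in '", path, "': not a TIFF (magic != 42)")
  ifd <- u32(4)
  n_ent <- u16(ifd)
  tags <- list()
  for (k in seq_len(n_ent)) {
    off <- ifd + 2 + (k - 1) * 12
    tag <- u16(off); typ <- u16(off + 2); cnt <- u32(off + 4)
    size <- TIFF_TYPE_SIZE[as.character(typ)]
    if (is.na(size)) next
    total <- size * cnt
    voff <- if (total > 4) u32(off + 8) else off + 8
    payload <- b[(voff + 1):(voff + total)]
    vals <- switch(as.character(typ),
      `2` = rawToChar(payload[payload != as.raw(0)]),
      `3` = readBin(payload, "integer", n = cnt, size = 2, endian = "little",
                    signed = FALSE),
      `4` = readBin(payload, "integer", n = cnt, size = 4, endian = "little"),
      `12` = readBin(payload, "double", n = cnt, size = 8, endian = "little"),
      payload)
    tags[[as.character(tag)]] <- vals
  }
  need <- c("256", "257", "258", "273", "279")
  if (!all(need %in% names(tags))) {
    stop("parse error in '", path, "': missing required TIFF tag(s)")
  }
  nc <- tags[["256"]]; nr <- tags[["257"]]; bits <- tags[["258"]]
  comp <- if (!is.null(tags[["259"]])) tags[["259"]] else 1
  if (comp != 1) stop("unsupported TIFF compression in '", path, "'")
  fmt <- if (!is.null(tags[["339"]])) tags[["339"]] else 1
  pix <- numeric(0)
  for (s in seq_along(tags[["273"]])) {
    so <- tags[["273"]][s]; sb <- tags[["279"]][s]
    chunk <- b[(so + 1):(so + sb)]
    pix <- c(pix, if (fmt == 3) {
      readBin(chunk, "double", n = sb / (bits / 8), size = bits / 8,
              endian = "little")
    } else {
      readBin(chunk, "integer", n = sb / (bits / 8), size = bits / 8,
              endian = "little")
    })
  }
  if (length(pix) != nr * nc) {
    stop("parse error in '", path, "': pixel count mismatch")
  }
  m <- matrix(pix, nrow = nr, ncol = nc, byrow = TRUE)
  cell_size <- if (!is.null(tags[["33550"]])) tags[["33550"]][1] else 1
  origin <- if (!is.null(tags[["33922"]])) tags[["33922"]][4:5] else c(0, nr * cell_size)
  crs_tag <- if (!is.null(tags[["34737"]])) tags[["34737"]] else "local"
  nodata <- if (!is.null(tags[["42113"]])) as.numeric(tags[["42113"]]) else -9999
  m[m == nodata] <- NA
  grid_raster(m, cell_size, origin, crs_tag, nodata)
}

# ---- GeoJSON ----

#' Write vector features as GeoJSON
#'
#' @param features list of features, each a list with `type` (`"Point"`,
#'   `"LineString"`, `"Polygon"`, `"MultiPolygon"`), `coordinates` (numeric
#'   vector/matrix/list following GeoJSON nesting), and optional `properties`
#'   (named list).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_geojson <- function(features, path) {
  fc <- list(
    type = "FeatureCollection",
    features = lapply(features, function(f) {
      list(type = "Feature",
           geometry = list(type = f$type, coordinates = f$coordinates),
           properties = if (is.null(f$properties)) setNames(list(), character(0))
                        else f$properties)
    })
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
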