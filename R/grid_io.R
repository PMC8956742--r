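#' Read a single-band raster
#'
#' Two dialects are supported: ESRI ASCII grid (`.asc`) and single-band
#' GeoTIFF (`.tif`/`.tiff`; classic little- or big-endian TIFF, uncompressed
#' strips, integer or IEEE floating-point samples, with
#' ModelPixelScale/ModelTiepoint georeferencing and the GDAL nodata tag).
#' Cells equal to the declared nodata value (or non-finite) are masked. A
#' file with no nodata declaration is read with all cells valid, with a
#' warning for the ASCII dialect where the header field is customary.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"ascii"` or `"geotiff"`.
#' @return an `ev_grid`.
#' @seealso [write_grid()]
#' @export
read_grid <- function(path, format = c("auto", "ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_ext(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format, ascii = read_ascii_grid(path), geotiff = read_geotiff(path))
}

#' Write a single-band raster
#'
#' @param grid an `ev_grid`.
#' @param path output file.
#' @param format `"auto"` (by extension), `"ascii"` or `"geotiff"`.
#' @param nodata sentinel written at masked cells. ASCII files record it in
#'   the `NODATA_value` header; GeoTIFF files record it in the GDAL nodata
#'   tag (the default `NaN` needs no sentinel in the data).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("auto", "ascii", "geotiff"),
                       nodata = NaN) {
  stopifnot(is_ev_grid(grid))
  format <- match.arg(format)
  if (format == "auto") format <- format_from_ext(path)
  switch(format,
         ascii = write_ascii_grid(grid, path, if (is.nan(nodata)) -9999 else nodata),
         geotiff = write_geotiff(grid, path, nodata))
  invisible(path)
}

format_from_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt")) return("ascii")
  if (ext %in% c("tif", "tiff")) return("geotiff")
  stop("cannot infer raster format from extension: ", path, call. = FALSE)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid

read_ascii_grid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("unexpected end of file in ", path, call. = FALSE)
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
    } else {
      seek(con, pos)
      break
    }
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k, call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows); cs <- hdr$cellsize
  vals <- scan(con, what = double(), n = nr * nc, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) {
    m[m == hdr$nodata_value] <- NA_real_
  } else {
    warning("no NODATA_value declared in ", path, "; all cells taken valid",
            call. = FALSE)
  }
  # header gives lower-left; center variants shift by half a cell
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  ev_grid(m, cell_size = cs, origin = c(xll, yll + nr * cs))
}

write_ascii_grid <- function(grid, path, nodata) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  m <- grid$values
  m[!grid$mask] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(grid$origin[1], digits = 15)),
    paste("yllcorner", format(grid$origin[2] - nr * cs, digits = 15)),
    paste("cellsize", format(cs, digits = 15)),
    paste("NODATA_value", format(nodata, digits = 15))), con)
  for (r in seq_len(nr))
    writeLines(paste(format(m[r, ], digits = 15, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
}

# ---------------------------------------------------------------------------
# Minimal single-band GeoTIFF codec (uncompressed, strip-organised).
# TIFF tag/type constants follow the TIFF 6.0 baseline plus the GeoTIFF
# ModelPixelScale (33550) / ModelTiepoint (33922), GeoAsciiParams (34737)
# and GDAL nodata (42113) extensions.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `6` = 1L,
                    `8` = 2L, `9` = 4L, `11` = 4L, `12` = 8L)

read_geotiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  bom <- rawToChar(raw[1:2])
  endian <- switch(bom, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  rd <- function(off, type, n) {
    sz <- switch(type, short = 2L, long = 4L, float = 4L, double = 8L, byte = 1L)
    what <- switch(type, short = "integer", long = "integer",
                   float = "double", double = "double", byte = "integer")
    readBin(raw[(off + 1):(off + sz * n)], what, n = n, size = sz,
            endian = endian, signed = !(type %in% c("short", "byte")))
  }
  if (rd(2, "short", 1) != 42L) stop("bad TIFF magic in ", path, call. = FALSE)
  ifd_off <- rd(4, "long", 1)
  n_entries <- rd(ifd_off, "short", 1)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd_off + 2 + (i - 1) * 12
    tag <- rd(e, "short", 1); type <- rd(e + 2, "short", 1)
    count <- rd(e + 4, "long", 1)
    sz <- TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(sz)) next
    total <- sz * count
    voff <- if (total <= 4) e + 8 else rd(e + 8, "long", 1)
    vals <- switch(as.character(type),
      `1` = rd(voff, "byte", count),
      `2` = rawToChar(raw[(voff + 1):(voff + count)]),
      `3` = rd(voff, "short", count),
      `4` = rd(voff, "long", count),
      `11` = rd(voff, "float", count),
      `12` = rd(voff, "double", count),
      NULL)
    if (!is.null(vals)) tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v) && is.null(default))
      stop("GeoTIFF missing required tag ", tag, " in ", path, call. = FALSE)
    if (is.null(v)) default else v
  }
  ncols <- need(256); nrows <- need(257)
  bits <- need(258, 32L); compression <- need(259, 1L)
  if (compression != 1L)
    stop("unsupported TIFF compression ", compression, " in ", path, call. = FALSE)
  if (need(277, 1L) != 1L)
    stop("only single-band TIFFs are supported: ", path, call. = FALSE)
  sample_format <- need(339, 1L)
  strip_offsets <- need(273); strip_counts <- need(279)
  bytes_px <- bits / 8
  what <- if (sample_format == 3L) "double" else "integer"
  signed <- sample_format != 1L || bits < 32   # readBin quirk: size-4 ints always signed
  data <- unlist(lapply(seq_along(strip_offsets), function(i) {
    o <- strip_offsets[i]; nb <- strip_counts[i]
    readBin(raw[(o + 1):(o + nb)], what, n = nb / bytes_px, size = bytes_px,
            endian = endian, signed = if (bits < 32) signed else TRUE)
  }))
  if (length(data) != nrows * ncols)
    stop("TIFF data size mismatch in ", path, call. = FALSE)
  m <- matrix(as.double(data), nrows, ncols, byrow = TRUE)
  nodata_tag <- tags[["42113"]]
  if (!is.null(nodata_tag)) {
    nd <- suppressWarnings(as.numeric(trimws(gsub("\\0", "", nodata_tag))))
    if (!is.na(nd)) m[m == nd] <- NA_real_
  }
  ps <- need(33550, c(1, 1, 0)); tp <- need(33922, rep(0, 6))
  crs <- tags[["34737"]]
  crs <- if (is.null(crs)) "" else gsub("\\0", "", crs)
  # tiepoint maps raster (i,j) to map (x,y); we require the upper-left anchor
  origin <- c(tp[4] - tp[1] * ps[1], tp[5] + tp[2] * ps[2])
  ev_grid(m, cell_size = ps[1], origin = origin, crs_tag = crs)
}

write_geotiff <- function(grid, path, nodata = NaN) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  m <- grid$values
  m[!grid$mask] <- nodata
  crs <- grid$crs_tag
  if (!nzchar(crs)) crs <- " "
  pad5 <- function(r) c(r, rep(as.raw(0), max(0L, 5L - length(r))))  # force out-of-line storage
  crs_raw <- pad5(c(charToRaw(crs), as.raw(0)))
  nd_str <- if (is.nan(nodata)) "nan" else format(nodata, digits = 17)
  nd_raw <- pad5(c(charToRaw(nd_str), as.raw(0)))

  entries <- list(  # tag, type, count, value (inline scalar or "offset")
    list(256L, 4L, 1L, nc), list(257L, 4L, 1L, nr),
    list(258L, 3L, 1L, 64L), list(259L, 3L, 1L, 1L),
    list(262L, 3L, 1L, 1L), list(273L, 4L, 1L, NA),   # strip offset, patched
    list(277L, 3L, 1L, 1L), list(278L, 4L, 1L, nr),
    list(279L, 4L, 1L, nr * nc * 8L), list(284L, 3L, 1L, 1L),
    list(339L, 3L, 1L, 3L),
    list(33550L, 12L, 3L, NA), list(33922L, 12L, 6L, NA),
    list(34737L, 2L, length(crs_raw), NA), list(42113L, 2L, length(nd_raw), NA))
  n_ent <- length(entries)
  ifd_off <- 8L
  ifd_size <- 2L + n_ent * 12L + 4L
  aux_off <- ifd_off + ifd_size
  ps_off <- aux_off                       # ModelPixelScale: 3 doubles
  tp_off <- ps_off + 24L                  # ModelTiepoint: 6 doubles
  crs_off <- tp_off + 48L
  nd_off <- crs_off + length(crs_raw)
  data_off <- nd_off + length(nd_raw)
  data_off <- data_off + (-data_off %% 4L)  # word-align pixel data

  con <- file(path, "wb"); on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L); w32(ifd_off)
  w16(n_ent)
  for (e in entries) {
    w16(e[[1]]); w16(e[[2]]); w32(e[[3]])
    val <- switch(as.character(e[[1]]),
      `273` = data_off, `33550` = ps_off, `33922` = tp_off,
      `34737` = crs_off, `42113` = nd_off, e[[4]])
    if (e[[2]] == 3L && is.na(match(e[[1]], c(33550L, 33922L, 34737L, 42113L)))) {
      w16(val); w16(0L)       # SHORT packed in the first 2 bytes
    } else w32(val)
  }
  w32(0L)  # next IFD
  writeBin(c(grid$cell_size, grid$cell_size, 0), con, size = 8, endian = "little")
  writeBin(c(0, 0, 0, grid$origin[1], grid$origin[2], 0), con,
           size = 8, endian = "little")
  writeBin(crs_raw, con)
  writeBin(nd_raw, con)
  pad <- data_off - (nd_off + length(nd_raw))
  if (pad > 0) writeBin(rep(as.raw(0), pad), con)
  writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  invisible(path)
}
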