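# Minimal single-band float32 GeoTIFF codec (geographic WGS84).
#
# Scope is deliberately narrow: uncompressed, single-band, 32-bit IEEE float
# rasters in geographic coordinates — the shape of every layer this pipeline
# reads or writes. Georeferencing uses the standard ModelPixelScale +
# ModelTiepoint tags, CRS is declared via a GeoKeyDirectory (EPSG:4326), and
# nodata via the GDAL_NODATA ASCII tag.

TIFF_TYPES <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L,
                SBYTE = 6L, UNDEF = 7L, SSHORT = 8L, SLONG = 9L,
                SRATIONAL = 10L, FLOAT = 11L, DOUBLE = 12L)
TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

DEFAULT_NODATA <- -3.4e+38

#' Write a raster grid as a single-band float32 GeoTIFF
#'
#' @param grid a [raster_grid()]; `NA` cells are written as the nodata value.
#' @param path output file path.
#' @param nodata numeric nodata value recorded in the file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = DEFAULT_NODATA) {
  stopifnot(inherits(grid, "raster_grid"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  v <- grid$values
  h <- nrow(v); w <- ncol(v)
  vals <- as.vector(t(v))            # row-major, row 1 (north) first
  vals[is.na(vals)] <- nodata

  data_bytes <- 4L * w * h
  ifd_offset <- 8L + data_bytes
  if (ifd_offset %% 2L == 1L) ifd_offset <- ifd_offset + 1L

  # record the float32-rounded nodata with full digits so strict readers can
  # cast it back to float32 exactly
  nodata_str <- c(charToRaw(format(float32_roundtrip(nodata), scientific = TRUE,
                                   digits = 17)), as.raw(0L))
  geokeys <- as.integer(c(1, 1, 0, 3,            # version, rev, minor, key count
                          1024, 0, 1, 2,          # GTModelType = geographic
                          1025, 0, 1, 1,          # GTRasterType = PixelIsArea
                          2048, 0, 1, 4326))      # GeographicType = WGS84
  pixel_scale <- c(grid$cell, grid$cell, 0)
  tiepoint <- c(0, 0, 0, grid$west, grid$north, 0)

  tags <- list(
    list(code = 256L, type = "LONG", values = w),
    list(code = 257L, type = "LONG", values = h),
    list(code = 258L, type = "SHORT", values = 32L),
    list(code = 259L, type = "SHORT", values = 1L),
    list(code = 262L, type = "SHORT", values = 1L),
    list(code = 273L, type = "LONG", values = 8L),
    list(code = 277L, type = "SHORT", values = 1L),
    list(code = 278L, type = "LONG", values = h),
    list(code = 279L, type = "LONG", values = data_bytes),
    list(code = 284L, type = "SHORT", values = 1L),
    list(code = 339L, type = "SHORT", values = 3L),
    list(code = 33550L, type = "DOUBLE", values = pixel_scale),
    list(code = 33922L, type = "DOUBLE", values = tiepoint),
    list(code = 34735L, type = "SHORT", values = geokeys),
    list(code = 42113L, type = "ASCII", values = nodata_str)
  )

  ifd_size <- 2L + length(tags) * 12L + 4L
  ext_offset <- ifd_offset + ifd_size
  ext_chunks <- list()
  for (i in seq_along(tags)) {
    tg <- tags[[i]]
    tid <- TIFF_TYPES[[tg$type]]
    n <- length(tg$values)
    nbytes <- n * TIFF_TYPE_SIZE[tid]
    if (nbytes > 4L) {
      tags[[i]]$offset <- ext_offset
      ext_chunks[[length(ext_chunks) + 1L]] <- tg
      ext_offset <- ext_offset + nbytes + (nbytes %% 2L)
    }
  }

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeBin(charToRaw("II"), con)
  wb(42L, 2L)
  wb(ifd_offset, 4L)
  wb(vals, 4L)                        # float32 image data at offset 8
  pad <- ifd_offset - (8L + data_bytes)
  if (pad > 0L) writeBin(as.raw(rep(0L, pad)), con)

  write_payload <- function(tg) {
    if (tg$type == "ASCII") writeBin(tg$values, con)
    else if (tg$type == "DOUBLE") wb(as.numeric(tg$values), 8L)
    else wb(as.integer(tg$values), TIFF_TYPE_SIZE[TIFF_TYPES[[tg$type]]])
  }
  wb(length(tags), 2L)
  for (tg in tags) {
    tid <- TIFF_TYPES[[tg$type]]
    n <- length(tg$values)
    nbytes <- n * TIFF_TYPE_SIZE[tid]
    wb(tg$code, 2L); wb(tid, 2L); wb(n, 4L)
    if (nbytes > 4L) {
      wb(tg$offset, 4L)
    } else {
      # inline: value left-justified in the 4-byte slot
      if (tg$type == "ASCII") {
        writeBin(c(tg$values, as.raw(rep(0L, 4L - nbytes))), con)
      } else {
        write_payload(tg)
        if (nbytes < 4L) writeBin(as.raw(rep(0L, 4L - nbytes)), con)
      }
    }
  }
  wb(0L, 4L)                          # no next IFD
  for (tg in ext_chunks) {
    write_payload(tg)
    tid <- TIFF_TYPES[[tg$type]]
    nbytes <- length(tg$values) * TIFF_TYPE_SIZE[tid]
    if (nbytes %% 2L == 1L) writeBin(as.raw(0L), con)
  }
  invisible(path)
}

#' Read a single-band float32 GeoTIFF into a raster grid
#'
#' @param path file path.
#' @return a [raster_grid()] with nodata as `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path, call. = FALSE)
  ru <- function(at, size, n = 1L, signed = TRUE) {
    readBin(raw[(at + 1L):(at + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  }
  if (ru(2L, 2L, signed = FALSE) != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  ifd <- ru(4L, 4L)
  n_tags <- ru(ifd, 2L, signed = FALSE)
  tags <- list()
  for (k in seq_len(n_tags)) {
    at <- ifd + 2L + (k - 1L) * 12L
    code <- ru(at, 2L, signed = FALSE)
    tid <- ru(at + 2L, 2L, signed = FALSE)
    cnt <- ru(at + 4L, 4L)
    sz <- TIFF_TYPE_SIZE[tid]
    nbytes <- sz * cnt
    off <- if (nbytes > 4L) ru(at + 8L, 4L) else at + 8L
    val <- switch(as.character(tid),
      "2" = read_cstring(raw[(off + 1L):(off + cnt)]),
      "3" = ru(off, 2L, cnt, signed = FALSE),
      "4" = ru(off, 4L, cnt),
      "11" = readBin(raw[(off + 1L):(off + nbytes)], "double", n = cnt,
                     size = 4L, endian = endian),
      "12" = readBin(raw[(off + 1L):(off + nbytes)], "double", n = cnt,
                     size = 8L, endian = endian),
      ru(off, sz, cnt))
    tags[[as.character(code)]] <- val
  }
  need <- function(code) {
    v <- tags[[as.character(code)]]
    if (is.null(v)) stop("TIFF tag ", code, " missing in ", path, call. = FALSE)
    v
  }
  w <- need(256L); h <- need(257L)
  if (!is.null(tags[["277"]]) && tags[["277"]] != 1L) {
    stop("multi-band TIFF not supported (single band expected): ", path, call. = FALSE)
  }
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1L) {
    stop("compressed TIFF not supported: ", path, call. = FALSE)
  }
  bits <- if (is.null(tags[["258"]])) 32L else tags[["258"]][1L]
  fmt <- if (is.null(tags[["339"]])) 3L else tags[["339"]][1L]
  if (!(bits == 32L && fmt == 3L)) {
    stop("only float32 sample format supported: ", path, call. = FALSE)
  }
  gk <- tags[["34735"]]
  if (!is.null(gk) && length(gk) >= 8L) {
    keys <- matrix(gk[-(1:4)], ncol = 4L, byrow = TRUE)
    mt <- keys[keys[, 1L] == 1024L, 4L]
    if (length(mt) == 1L && mt != 2L) {
      stop("non-geographic CRS in ", path, " (projected rasters not supported)",
           call. = FALSE)
    }
  }
  offsets <- need(273L); counts <- need(279L)
  vals <- numeric(0L)
  for (s in seq_along(offsets)) {
    vals <- c(vals, readBin(raw[(offsets[s] + 1L):(offsets[s] + counts[s])],
                            "double", n = counts[s] / 4L, size = 4L,
                            endian = endian))
  }
  if (length(vals) != w * h) stop("truncated raster data in ", path, call. = FALSE)
  scale <- need(33550L); tie <- need(33922L)
  if (abs(scale[1L] - scale[2L]) > 1e-9 * max(scale[1:2])) {
    stop("non-square cells not supported: ", path, call. = FALSE)
  }
  nodata <- if (!is.null(tags[["42113"]])) as.numeric(tags[["42113"]]) else NA_real_
  if (!is.na(nodata)) {
    nodata32 <- float32_roundtrip(nodata)
    tol <- max(abs(nodata32) * 1e-6, 1e-12)
    vals[abs(vals - nodata32) <= tol] <- NA_real_
  }
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  raster_grid(m, west = tie[4L] - tie[1L] * scale[1L],
              north = tie[5L] + tie[2L] * scale[2L], cell = scale[1L])
}

read_cstring <- function(r) {
  z <- which(r == as.raw(0L))
  if (length(z)) r <- r[seq_len(z[1L] - 1L)]
  rawToChar(r)
}

float32_roundtrip <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}
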