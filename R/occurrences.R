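#' Read an occurrence table (Lon, Lat in decimal degrees)
#'
#' Delimited text with columns `Lon`/`Lat` (case-insensitive; `longitude`/
#' `latitude` also accepted). Rows with unparsable or out-of-range
#' coordinates are dropped with a message; exact duplicate coordinates are
#' collapsed to one record.
#'
#' @param path path to a delimited text file (separator sniffed among
#'   comma, semicolon, tab).
#' @param species_id optional species identifier attached as an attribute
#'   and column.
#' @return tibble with columns `species_id` (if given), `lon`, `lat`.
#' @export
read_occurrences <- function(path, species_id = NULL) {
  if (!file.exists(path)) stop("occurrence file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- c(",", ";", "\t")[which.max(vapply(c(",", ";", "\t"), function(s)
    lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))), numeric(1)))]
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  nms <- tolower(names(df))
  ilon <- match(TRUE, nms %in% c("lon", "longitude", "x"))
  ilat <- match(TRUE, nms %in% c("lat", "latitude", "y"))
  if (is.na(ilon) || is.na(ilat)) {
    stop("missing required columns Lon/Lat in ", path, call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(df[[ilon]]))
  lat <- suppressWarnings(as.numeric(df[[ilat]]))
  ok <- !is.na(lon) & !is.na(lat) & lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  if (any(!ok)) {
    message(sum(!ok), " record(s) dropped (unparsable or out-of-range coordinates)")
  }
  out <- tibble::tibble(lon = lon[ok], lat = lat[ok])
  out <- dplyr::distinct(out)
  if (!is.null(species_id)) {
    out <- dplyr::mutate(out, species_id = species_id, .before = 1L)
    attr(out, "species_id") <- species_id
  }
  out
}

#' Write an occurrence table as CSV with header `Lon,Lat`
#'
#' @param occ data frame with `lon`, `lat` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  pts <- normalize_lonlat(occ)
  utils::write.csv(data.frame(Lon = pts$lon, Lat = pts$lat), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
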