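#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Handles antimeridian
#' wrap correctly (geosphere works on the sphere, not on raw longitude
#' differences).
#'
#' @param a,b coordinates: length-2 numeric `c(lon, lat)` or two-column
#'   matrices/data frames (lon, lat) in decimal degrees. Vectorised with the
#'   usual recycling.
#' @return numeric vector of distances in km.
#' @export
great_circle_km <- function(a, b) {
  geosphere::distHaversine(as_lonlat_matrix(a), as_lonlat_matrix(b),
                           r = 6371) # km
}

as_lonlat_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(normalize_lonlat(p))
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("coordinates must be (lon, lat) pairs", call. = FALSE)
  if (any(stats::na.omit(abs(p[, 2L])) > 90) || any(stats::na.omit(abs(p[, 1L])) > 360)) {
    stop("coordinates out of range: need lon in [-360, 360], lat in [-90, 90]",
         call. = FALSE)
  }
  p
}

#' Pairwise great-circle distance matrix (km)
#'
#' @param a,b two-column (lon, lat) matrices or data frames.
#' @return length(a)-by-length(b) matrix of km distances.
#' @export
great_circle_matrix_km <- function(a, b) {
  geosphere::distm(as_lonlat_matrix(a), as_lonlat_matrix(b),
                   fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371))
}
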