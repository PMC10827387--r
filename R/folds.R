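# Spatial-block cross-validation folds from a hexagonal tessellation.
# Points are projected onto a local equirectangular plane (km) centered on
# their median coordinate, assigned to flat-topped hexagons whose
# across-flats width equals the uncorrelated distance, and occupied hexagons
# are dealt round-robin to folds after a seeded shuffle — so records sharing
# a hexagon can never cross folds.

KM_PER_DEG <- 111.32

local_km_xy <- function(lon, lat, lon0, lat0) {
  cbind(x = (lon - lon0) * KM_PER_DEG * cos(lat0 * pi / 180),
        y = (lat - lat0) * KM_PER_DEG)
}

# Axial coordinates of flat-topped hexagons; size = circumradius,
# across-flats width = sqrt(3) * size.
hex_axial <- function(xy, size) {
  q <- (2 / 3) * xy[, 1L] / size
  r <- (-1 / 3 * xy[, 1L] + sqrt(3) / 3 * xy[, 2L]) / size
  hex_round(q, r)
}

hex_round <- function(q, r) {
  x <- q; z <- r; y <- -x - z
  rx <- round(x); ry <- round(y); rz <- round(z)
  dx <- abs(rx - x); dy <- abs(ry - y); dz <- abs(rz - z)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cbind(q = as.integer(rx), r = as.integer(rz))
}

#' Assign points to hexagonal spatial cross-validation folds
#'
#' @param points data frame with `lon`, `lat`.
#' @param hex_width_km across-flats width of the hexagons, km (normally the
#'   uncorrelated distance from [estimate_autocorrelation_distance()]).
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed for the hexagon shuffle.
#' @return tibble with one row per point: `lon`, `lat`, `hex_id`, `fold`.
#' @export
assign_hex_folds <- function(points, hex_width_km, n_folds = 10, seed = 1) {
  pts <- normalize_lonlat(points)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (hex_width_km <= 0) stop("hex_width_km must be positive", call. = FALSE)
  lon0 <- stats::median(pts$lon); lat0 <- stats::median(pts$lat)
  xy <- local_km_xy(pts$lon, pts$lat, lon0, lat0)
  ax <- hex_axial(xy, size = hex_width_km / sqrt(3))
  hex_id <- paste(ax[, "q"], ax[, "r"], sep = ":")
  hexes <- sort(unique(hex_id))
  if (length(hexes) < n_folds) {
    stop(length(hexes), " occupied hexagon(s) < ", n_folds,
         " folds; reduce n_folds or hex width", call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(hexes))
  fold_of <- stats::setNames(rep(seq_len(n_folds), length.out = length(shuffled)),
                             shuffled)
  tibble::tibble(lon = pts$lon, lat = pts$lat, hex_id = hex_id,
                 fold = as.integer(fold_of[hex_id]))
}

#' Add hexagon-block folds to a training set
#'
#' Computes the hexagon tessellation on the rows of a training set
#' (presences and pseudo-absences together, per run) and appends a `fold`
#' column. So that every fold can be evaluated, hexagons containing at
#' least one presence are dealt round-robin across folds first, then
#' absence-only hexagons; when fewer presence hexagons than folds are
#' occupied the fold count is reduced to that number (never below 2), with
#' a message.
#'
#' @param train training tibble with `lon`, `lat`, `label` (and optionally
#'   `run`).
#' @param hex_width_km across-flats hexagon width, km.
#' @param n_folds requested number of folds.
#' @param seed integer seed.
#' @return `train` with a `fold` column (integer).
#' @export
add_hex_folds <- function(train, hex_width_km, n_folds = 10, seed = 1) {
  if (!"run" %in% names(train)) train$run <- 1L
  if (!"label" %in% names(train)) train$label <- 1L
  out <- dplyr::group_split(dplyr::group_by(train, .data$run))
  out <- purrr::map(out, function(tr) {
    run_seed <- seed + tr$run[1L]
    pts <- normalize_lonlat(tr)
    lon0 <- stats::median(pts$lon); lat0 <- stats::median(pts$lat)
    ax <- hex_axial(local_km_xy(pts$lon, pts$lat, lon0, lat0),
                    size = hex_width_km / sqrt(3))
    hex_id <- paste(ax[, "q"], ax[, "r"], sep = ":")
    pres_hex <- sort(unique(hex_id[tr$label == 1L]))
    abs_hex <- setdiff(sort(unique(hex_id)), pres_hex)
    k <- min(n_folds, length(pres_hex))
    if (k < 2) {
      stop("fewer than 2 hexagons contain presences; cannot build spatial folds",
           call. = FALSE)
    }
    if (k < n_folds) {
      message("only ", length(pres_hex), " presence hexagon(s); using ",
              k, " folds")
    }
    dealt <- withr::with_seed(run_seed, c(sample(pres_hex),
                                          if (length(abs_hex)) sample(abs_hex)))
    fold_of <- stats::setNames(rep(seq_len(k), length.out = length(dealt)),
                               dealt)
    tr$fold <- as.integer(fold_of[hex_id])
    tr
  })
  dplyr::bind_rows(out)
}
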