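# Binary range maps: thresholding the ensemble suitability at the
# minimum-training-area threshold, restricting to the species' maximum
# known depth, and removing suitable patches unreachable from occupied
# habitat by chained dispersal steps (stepping-stone reachability with a
# fixed maximum step, default 200 km). A gap of unsuitable habitat wider
# than the maximum step is impassable unless occurrence records demonstrate
# presence beyond it.

range_map_grid <- function(values, ref, scenario = NULL, threshold = NA_real_,
                           clips = character(0)) {
  g <- raster_grid(values, ref$west, ref$north, ref$cell)
  attr(g, "scenario") <- scenario
  attr(g, "threshold") <- threshold
  attr(g, "clips") <- clips
  class(g) <- c("range_map", class(g))
  g
}

#' @export
print.range_map <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<range_map> %d x %d; %d presence cells; threshold %s; clips: %s\n",
    nrow(v), ncol(v), sum(v == 1, na.rm = TRUE),
    format(attr(x, "threshold")),
    if (length(attr(x, "clips"))) paste(attr(x, "clips"), collapse = " -> ")
    else "none"))
  invisible(x)
}

#' Reclassify a suitability map into a binary range map
#'
#' Presence iff suitability >= threshold; nodata untouched.
#'
#' @param suitability a suitability [raster_grid()].
#' @param threshold threshold in `[0, 1]` (normally from
#'   [mtp_threshold()]).
#' @param scenario optional scenario label recorded in the map's
#'   provenance.
#' @return a `range_map` (binary [raster_grid()] with provenance
#'   attributes).
#' @export
reclassify <- function(suitability, threshold, scenario = NULL) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  v <- suitability$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  range_map_grid(out, suitability, scenario, threshold, clips = "mtp")
}

#' Restrict a range map to the species' maximum known depth
#'
#' @param range_map a `range_map`.
#' @param bathymetry co-registered [raster_grid()] of depth (m, positive
#'   down).
#' @param max_depth_m maximum known depth (> 0); deeper cells become
#'   absences.
#' @return the clipped `range_map`.
#' @export
clip_depth <- function(range_map, bathymetry, max_depth_m) {
  stop_if_mismatch(range_map, bathymetry, "bathymetry")
  if (max_depth_m <= 0) stop("max_depth_m must be positive", call. = FALSE)
  v <- range_map$values
  deep <- which(bathymetry$values > max_depth_m & v == 1)
  v[deep] <- 0
  range_map_grid(v, range_map, attr(range_map, "scenario"),
                 attr(range_map, "threshold"),
                 clips = union(attr(range_map, "clips"), "depth"))
}

#' Remove presence cells unreachable by chained dispersal steps
#'
#' Seeds are presence cells containing at least one occurrence record, plus
#' all occurrence cells regardless of predicted state (occurrence records
#' demonstrate that a region was reached). The reached set then grows
#' iteratively: a presence cell joins when its great-circle distance to any
#' reached cell is at most `max_step_km`; at the fixpoint, presence cells
#' never reached become absences. Alternatively `seed_cells` (linear cell
#' indices) can seed the expansion directly — used to seed future scenarios
#' from the baseline clipped range.
#'
#' @param range_map a `range_map`.
#' @param occurrences occurrence tibble (`lon`, `lat`); ignored when
#'   `seed_cells` is given.
#' @param max_step_km maximum dispersal step, km (default 200).
#' @param seed_cells optional integer vector of linear cell indices.
#' @return the clipped `range_map`.
#' @export
clip_dispersal <- function(range_map, occurrences = NULL, max_step_km = 200,
                           seed_cells = NULL) {
  if (max_step_km <= 0) stop("max_step_km must be positive", call. = FALSE)
  v <- range_map$values
  pres <- which(v == 1)
  if (is.null(seed_cells)) {
    if (is.null(occurrences) || !nrow(occurrences)) {
      warning("no occurrences to seed dispersal clipping; map returned unchanged")
      return(range_map)
    }
    occ <- normalize_lonlat(occurrences)
    loc <- locate_cells(range_map, occ$lon, occ$lat)
    seed_cells <- unique(loc$cell[loc$inside])
  }
  out_clips <- union(attr(range_map, "clips"), "dispersal")
  if (!length(pres) || !length(seed_cells)) {
    v[pres] <- 0
    return(range_map_grid(v, range_map, attr(range_map, "scenario"),
                          attr(range_map, "threshold"), out_clips))
  }
  # nodes = presence cells plus seed cells (occurrence cells join the
  # reachable set even where the model predicts absence)
  nodes <- union(pres, seed_cells)
  cc <- cell_centers(range_map, nodes)
  reached <- nodes %in% seed_cells
  frontier <- which(reached)
  lat_pad <- max_step_km / 111.32 * 1.001
  while (length(frontier)) {
    todo <- which(!reached)
    if (!length(todo)) break
    new_hits <- integer(0)
    for (fi in frontier) {
      if (!length(todo)) break
      near <- todo[abs(cc$lat[todo] - cc$lat[fi]) <= lat_pad]
      if (!length(near)) next
      d <- great_circle_km(cbind(cc$lon[near], cc$lat[near]),
                           c(cc$lon[fi], cc$lat[fi]))
      hit <- near[d <= max_step_km]
      if (length(hit)) {
        reached[hit] <- TRUE
        new_hits <- c(new_hits, hit)
        todo <- setdiff(todo, hit)
      }
    }
    frontier <- new_hits
  }
  lost <- nodes[!reached]
  v[intersect(lost, pres)] <- 0
  range_map_grid(v, range_map, attr(range_map, "scenario"),
                 attr(range_map, "threshold"), out_clips)
}

#' Project an ensemble across scenarios with thresholding and clipping
#'
#' Per scenario produces the suitability map, the uncertainty map, and the
#' binary range map after minimum-training-area thresholding, depth
#' restriction and dispersal clipping. The threshold is fixed from the
#' baseline training and reused for future scenarios; future dispersal
#' expansion is seeded from the baseline clipped range, so colonization is
#' limited to cells reachable from currently occupied habitat.
#'
#' @param ensemble an `sdm_ensemble` with its `threshold` set.
#' @param stacks named list of [predictor_stack()]s; must include
#'   `"baseline"`.
#' @param occurrences occurrence tibble used to seed baseline dispersal.
#' @param bathymetry optional co-registered bathymetry [raster_grid()];
#'   depth clipping is skipped when `NULL` or when the ensemble has no
#'   finite maximum depth.
#' @param max_step_km maximum dispersal step, km.
#' @param apply_dispersal set `FALSE` to skip dispersal clipping.
#' @return named list per scenario, each with `suitability`,
#'   `uncertainty`, `range`.
#' @export
project_scenarios <- function(ensemble, stacks, occurrences,
                              bathymetry = NULL, max_step_km = 200,
                              apply_dispersal = TRUE) {
  stopifnot(inherits(ensemble, "sdm_ensemble"))
  if (!"baseline" %in% names(stacks)) {
    stop("stacks must include a 'baseline' scenario", call. = FALSE)
  }
  if (is.na(ensemble$threshold)) {
    stop("ensemble has no reclassification threshold set", call. = FALSE)
  }
  for (sc in names(stacks)) {
    missing <- setdiff(ensemble$features, stack_names(stacks[[sc]]))
    if (length(missing)) {
      stop("scenario '", sc, "' is missing layer(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  do_depth <- !is.null(bathymetry) && is.finite(ensemble$max_depth_m)
  clip_one <- function(suit, scenario, seed_cells = NULL) {
    rm <- reclassify(suit, ensemble$threshold, scenario)
    if (do_depth) rm <- clip_depth(rm, bathymetry, ensemble$max_depth_m)
    if (apply_dispersal) {
      rm <- if (is.null(seed_cells)) {
        clip_dispersal(rm, occurrences, max_step_km)
      } else {
        clip_dispersal(rm, max_step_km = max_step_km, seed_cells = seed_cells)
      }
    }
    rm
  }
  base_pred <- ensemble_predict(ensemble, stacks[["baseline"]])
  base_range <- clip_one(base_pred$suitability, "baseline")
  out <- list(baseline = c(base_pred, list(range = base_range)))
  base_seed <- which(base_range$values == 1)
  for (sc in setdiff(names(stacks), "baseline")) {
    pred <- ensemble_predict(ensemble, stacks[[sc]])
    out[[sc]] <- c(pred, list(range = clip_one(pred$suitability, sc,
                                               seed_cells = base_seed)))
  }
  out
}

#' Range area as a cell count and fraction
#'
#' @param range_map a `range_map`.
#' @return tibble with `n_presence`, `n_unmasked`, `fraction`.
#' @export
range_area <- function(range_map) {
  v <- range_map$values
  n1 <- sum(v == 1, na.rm = TRUE); n <- sum(!is.na(v))
  tibble::tibble(n_presence = n1, n_unmasked = n, fraction = n1 / n)
}
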