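# Synthetic worlds: spatially autocorrelated predictor fields, bathymetry,
# a land mask and additive future scenarios, plus virtual species with known
# trapezoidal tolerance limits. These give every downstream stage a
# desk-scale test bed with ground truth; no real environmental layers are
# required anywhere in the package's tests.

PREDICTOR_VOCAB <- c("temp_max", "temp_min", "sea_ice", "nitrate", "salinity",
                     "ph", "phytoplankton", "oxygen", "water_speed", "slope",
                     "ruggedness", "wave_energy")
STATIC_PREDICTORS <- c("slope", "ruggedness", "wave_energy")
SCENARIO_LABELS <- c("baseline", "ssp119", "ssp370", "ssp585")

#' Specification of one synthetic predictor field
#'
#' @param name predictor name from the package vocabulary (see
#'   [default_predictor_specs()]).
#' @param mean,sd target mean and spatial standard deviation of the field,
#'   in the predictor's units.
#' @param lat_gradient additive trend per degree latitude (units/degree);
#'   e.g. a negative value makes ocean temperature warmer toward the south
#'   edge of a northern-hemisphere grid.
#' @return a list usable in `predictor_specs` of [make_world()].
#' @export
predictor_spec <- function(name, mean, sd, lat_gradient = 0) {
  if (!name %in% PREDICTOR_VOCAB) {
    stop("unknown predictor name '", name, "'; known: ",
         paste(PREDICTOR_VOCAB, collapse = ", "), call. = FALSE)
  }
  list(name = name, mean = mean, sd = sd, lat_gradient = lat_gradient,
       static = name %in% STATIC_PREDICTORS)
}

#' Default synthetic predictor set (marine-forest flavour)
#'
#' Maximum/minimum ocean temperature with a latitudinal gradient, salinity,
#' nitrate, and two static seafloor layers. Units follow the field's
#' conventions (temperature in degrees C, nitrate in mol m-3, wave energy
#' and slope unitless indices).
#'
#' @return named list of [predictor_spec()]s.
#' @export
default_predictor_specs <- function() {
  specs <- list(
    predictor_spec("temp_max", mean = 18, sd = 2.5, lat_gradient = -0.4),
    predictor_spec("temp_min", mean = 11, sd = 2.0, lat_gradient = -0.4),
    predictor_spec("salinity", mean = 35, sd = 1.0),
    predictor_spec("nitrate", mean = 5, sd = 1.5),
    predictor_spec("wave_energy", mean = 10, sd = 3.0),
    predictor_spec("slope", mean = 5, sd = 2.0)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Default additive scenario offsets (end-of-century warming)
#'
#' Dynamic layers only; magnitudes follow the ordering of the SSP forcing
#' levels (SSP1-1.9 mild, SSP5-8.5 strong warming).
#'
#' @return named list: scenario -> named numeric vector of additive shifts.
#' @export
default_scenario_offsets <- function() {
  list(
    ssp119 = c(temp_max = 1.0, temp_min = 1.0),
    ssp370 = c(temp_max = 2.8, temp_min = 2.8),
    ssp585 = c(temp_max = 4.5, temp_min = 4.5)
  )
}

# Standardized Gaussian random field via separable Gaussian smoothing of
# white noise on a padded lattice (pad = 3 sd, cropped back), so edge cells
# have the same correlation structure as interior cells.
smooth_field <- function(n_rows, n_cols, sd_cells) {
  if (sd_cells <= 0) {
    f <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  } else {
    pad <- ceiling(3 * sd_cells)
    k <- stats::dnorm(seq(-pad, pad), sd = sd_cells)
    k <- k / sum(k)
    z <- matrix(stats::rnorm((n_rows + 2 * pad) * (n_cols + 2 * pad)),
                n_rows + 2 * pad, n_cols + 2 * pad)
    z <- apply(z, 2L, function(col) as.numeric(stats::filter(col, k, sides = 2)))
    z <- t(apply(z, 1L, function(row) as.numeric(stats::filter(row, k, sides = 2))))
    f <- z[(pad + 1L):(pad + n_rows), (pad + 1L):(pad + n_cols)]
  }
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic world
#'
#' Builds co-registered predictor fields (smoothed Gaussian random fields
#' with a controllable correlation length, plus optional latitudinal
#' gradients), a bathymetry layer, a land mask, and additive future
#' scenarios. The kernel sd in cells is
#' `autocorr_length_km / (111.32 * cell_deg)`.
#'
#' @param n_rows,n_cols grid dimensions (each >= 8).
#' @param cell_deg cell size in decimal degrees.
#' @param predictor_specs named list of [predictor_spec()]s.
#' @param autocorr_length_km spatial correlation length of the random
#'   fields, km (0 = white noise).
#' @param scenario_offsets named list scenario -> named numeric additive
#'   shifts for dynamic predictors (see [default_scenario_offsets()]).
#' @param seed integer seed; worlds are pure functions of their arguments.
#' @param west,north west / north edge of the grid in degrees. By default
#'   the grid straddles the equator at `west = 0`.
#' @param land_fraction fraction of cells masked as land/nodata.
#' @param depth_range range of water depth (m, positive down) spanned by
#'   the synthetic bathymetry.
#' @return an object of class `synthetic_world`.
#' @export
make_world <- function(n_rows = 200, n_cols = 200, cell_deg = 0.05,
                       predictor_specs = default_predictor_specs(),
                       autocorr_length_km = 30,
                       scenario_offsets = default_scenario_offsets(),
                       seed = 1, west = 0, north = NULL,
                       land_fraction = 0.15, depth_range = c(5, 1000)) {
  if (n_rows < 8 || n_cols < 8) stop("grid must be at least 8 x 8", call. = FALSE)
  if (cell_deg <= 0) stop("cell_deg must be positive", call. = FALSE)
  if (autocorr_length_km < 0) stop("autocorr_length_km must be >= 0", call. = FALSE)
  nms <- vapply(predictor_specs, `[[`, "", "name")
  if (any(!nms %in% PREDICTOR_VOCAB)) {
    stop("unknown predictor name(s): ", paste(setdiff(nms, PREDICTOR_VOCAB),
                                              collapse = ", "), call. = FALSE)
  }
  names(predictor_specs) <- nms
  for (sc in names(scenario_offsets)) {
    off <- scenario_offsets[[sc]]
    bad <- intersect(names(off), STATIC_PREDICTORS)
    if (length(bad)) {
      stop("static predictor(s) cannot shift across scenarios: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(!names(off) %in% nms)) {
      stop("scenario '", sc, "' shifts unknown predictor(s): ",
           paste(setdiff(names(off), nms), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(north)) north <- n_rows * cell_deg / 2

  sd_cells <- autocorr_length_km / (111.32 * cell_deg)
  lat <- north - (seq_len(n_rows) - 0.5) * cell_deg
  lat_dev <- matrix(lat - mean(lat), n_rows, n_cols)

  withr::with_seed(seed, {
    land_field <- smooth_field(n_rows, n_cols, max(sd_cells, 2))
    land <- land_field > stats::quantile(land_field, 1 - land_fraction)
    bathy_field <- smooth_field(n_rows, n_cols, max(sd_cells, 2))
    bathymetry <- depth_range[1] +
      (depth_range[2] - depth_range[1]) * stats::pnorm(bathy_field)
    predictors <- lapply(predictor_specs, function(sp) {
      f <- smooth_field(n_rows, n_cols, sd_cells)
      v <- sp$mean + sp$sd * f + sp$lat_gradient * lat_dev
      v[land] <- NA_real_
      v
    })
  })
  bathymetry[land] <- NA_real_

  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell = cell_deg,
         west = west, north = north,
         specs = predictor_specs, predictors = predictors,
         bathymetry = bathymetry, land = land,
         scenario_offsets = scenario_offsets,
         autocorr_length_km = autocorr_length_km, seed = seed),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d x %d @ %g deg; predictors: %s\n  scenarios: %s; %d land cells; seed %d\n",
    x$n_rows, x$n_cols, x$cell, paste(names(x$predictors), collapse = ", "),
    paste(c("baseline", names(x$scenario_offsets)), collapse = ", "),
    sum(x$land), x$seed))
  invisible(x)
}

world_grid <- function(world, values) {
  raster_grid(values, west = world$west, north = world$north, cell = world$cell)
}

#' Predictor stack of a synthetic world for one scenario
#'
#' Future layers equal baseline plus the scenario's additive offset for
#' dynamic predictors; static layers (slope, ruggedness, wave energy) are
#' identical across scenarios.
#'
#' @param world a [make_world()] object.
#' @param scenario `"baseline"` or a name of `world$scenario_offsets`.
#' @return a [predictor_stack()].
#' @export
world_stack <- function(world, scenario = "baseline") {
  stopifnot(inherits(world, "synthetic_world"))
  if (!identical(scenario, "baseline") &&
      !scenario %in% names(world$scenario_offsets)) {
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  }
  off <- if (identical(scenario, "baseline")) numeric(0)
         else world$scenario_offsets[[scenario]]
  grids <- lapply(names(world$predictors), function(nm) {
    v <- world$predictors[[nm]]
    if (nm %in% names(off)) v <- v + off[[nm]]
    world_grid(world, v)
  })
  names(grids) <- names(world$predictors)
  predictor_stack(grids, scenario = scenario)
}

#' Bathymetry layer of a synthetic world
#'
#' @param world a [make_world()] object.
#' @return a [raster_grid()] of water depth (m, positive down).
#' @export
world_bathymetry <- function(world) {
  world_grid(world, world$bathymetry)
}

#' Write a synthetic world to GeoTIFF files
#'
#' One file per predictor per scenario (`<predictor>_<scenario>.tif`) plus
#' `bathymetry.tif`.
#'
#' @param world a [make_world()] object.
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sc in c("baseline", names(world$scenario_offsets))) {
    st <- world_stack(world, sc)
    for (nm in names(st$grids)) {
      f <- file.path(dir, paste0(nm, "_", sc, ".tif"))
      write_raster(st$grids[[nm]], f)
      files <- c(files, f)
    }
  }
  f <- file.path(dir, "bathymetry.tif")
  write_raster(world_bathymetry(world), f)
  invisible(c(files, f))
}

trapezoid_response <- function(x, knots) {
  a <- knots[1]; b <- knots[2]; c_ <- knots[3]; d <- knots[4]
  y <- numeric(length(x))
  y[which(x >= b & x <= c_)] <- 1
  ramp <- which(x > a & x < b)
  if (b > a) y[ramp] <- (x[ramp] - a) / (b - a)
  ramp <- which(x > c_ & x < d)
  if (d > c_) y[ramp] <- (d - x[ramp]) / (d - c_)
  y[is.na(x)] <- NA_real_
  y
}

#' Create a virtual species with known tolerance limits
#'
#' True habitat suitability is the cell-wise product of piecewise
#' trapezoidal responses, one per predictor: 0 outside `[lower, upper]`,
#' 1 on `[opt_lo, opt_hi]`, linear ramps between. The trapezoid support
#' edges are recorded as the species' true tipping points (side `min` for
#' the lower limit, `max` for the upper limit).
#'
#' @param world a [make_world()] object.
#' @param response_params named list: predictor -> numeric
#'   `c(lower, opt_lo, opt_hi, upper)` in predictor units (use `-Inf`/`Inf`
#'   for one-sided responses).
#' @param max_depth_m maximum known depth of the species (m).
#' @return an object of class `virtual_species`.
#' @export
make_virtual_species <- function(world, response_params, max_depth_m = Inf) {
  stopifnot(inherits(world, "synthetic_world"))
  missing <- setdiff(names(response_params), names(world$predictors))
  if (length(missing)) {
    stop("response predictors not in world: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(response_params)) {
    k <- response_params[[nm]]
    if (length(k) != 4L || is.unsorted(k)) {
      stop("trapezoid knots for '", nm,
           "' must be 4 non-decreasing values (lower, opt_lo, opt_hi, upper)",
           call. = FALSE)
    }
  }
  suit <- matrix(1, world$n_rows, world$n_cols)
  for (nm in names(response_params)) {
    suit <- suit * trapezoid_response(world$predictors[[nm]],
                                      response_params[[nm]])
  }
  suit[world$land] <- NA_real_
  tp <- purrr::map_dfr(names(response_params), function(nm) {
    k <- response_params[[nm]]
    tibble::tibble(predictor = nm, side = c("min", "max"),
                   value = c(k[1], k[4]))
  })
  tp <- dplyr::filter(tp, is.finite(.data$value))
  structure(
    list(world = world, responses = response_params,
         suitability = matrix(suit, world$n_rows, world$n_cols),
         tipping_points = tp, max_depth_m = max_depth_m),
    class = "virtual_species"
  )
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species> responds to: %s; max depth %g m\n",
              paste(names(x$responses), collapse = ", "), x$max_depth_m))
  cat(sprintf("  suitable cells: %d of %d unmasked\n",
              sum(x$suitability > 0, na.rm = TRUE), sum(!is.na(x$suitability))))
  invisible(x)
}

#' True suitability of a virtual species as a raster grid
#'
#' @param species a [make_virtual_species()] object.
#' @return a [raster_grid()] with values in `[0, 1]`.
#' @export
true_suitability <- function(species) {
  world_grid(species$world, species$suitability)
}

#' Sample biased occurrence records of a virtual species
#'
#' Draws `n` records (with replacement) from unmasked cells with positive
#' suitability, with probability proportional to `suitability^bias_exponent`;
#' `bias_exponent = 0` samples uniformly over suitable cells, larger values
#' concentrate records near the niche optimum (emulating sampling bias).
#' Coordinates snap to cell centers.
#'
#' @param species a [make_virtual_species()] object.
#' @param n number of records (>= 1).
#' @param bias_exponent non-negative exponent on suitability.
#' @param seed integer seed.
#' @return tibble with `lon`, `lat`.
#' @export
sample_occurrences <- function(species, n, bias_exponent = 1, seed = 1) {
  stopifnot(inherits(species, "virtual_species"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  suit <- species$suitability
  cells <- which(!is.na(suit) & suit > 0)
  if (!length(cells)) stop("no cell with positive suitability", call. = FALSE)
  prob <- suit[cells]^bias_exponent
  ref <- true_suitability(species)
  idx <- withr::with_seed(seed,
    cells[sample.int(length(cells), n, replace = TRUE, prob = prob)])
  cc <- cell_centers(ref, idx)
  tibble::tibble(lon = cc$lon, lat = cc$lat)
}
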