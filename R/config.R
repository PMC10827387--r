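# Per-species configuration. Default predictor sets per group follow the
# standard predictor-to-group mapping: the marine-forest groups
# (seagrasses, kelps, fucoids) use temperature extremes, sea ice, nitrate,
# salinity and wave energy; cold-water corals use temperature extremes,
# salinity, pH, phytoplankton, oxygen, water speed, slope and ruggedness.

SPECIES_GROUPS <- c("seagrass", "kelp", "fucoid", "cold-water coral")

#' Default predictors for a species group
#'
#' @param group one of `"seagrass"`, `"kelp"`, `"fucoid"`,
#'   `"cold-water coral"`.
#' @return character vector of predictor names.
#' @export
group_predictors <- function(group) {
  group <- match.arg(group, SPECIES_GROUPS)
  if (group == "cold-water coral") {
    c("temp_max", "temp_min", "salinity", "ph", "phytoplankton", "oxygen",
      "water_speed", "slope", "ruggedness")
  } else {
    c("temp_max", "temp_min", "sea_ice", "nitrate", "salinity", "wave_energy")
  }
}

#' Build a species configuration for the modelling pipeline
#'
#' @param species_id species identifier (used in output file names).
#' @param group species group; sets the default predictor list.
#' @param occurrences occurrence tibble (`lon`, `lat`) or path to a
#'   `Lon,Lat` delimited file.
#' @param world a [make_world()] object supplying the predictor stacks, or
#'   `NULL` when `stacks` is given.
#' @param stacks named list of [predictor_stack()]s (must include
#'   `"baseline"`); overrides `world`.
#' @param bathymetry bathymetry [raster_grid()]; taken from `world` when
#'   omitted.
#' @param predictors predictor names to model with (default: the group's
#'   set intersected with the available layers).
#' @param monotone named +1/-1 directions (default
#'   [default_monotone_map()]).
#' @param max_depth_m maximum known depth (m) for depth clipping.
#' @param scenarios future scenario labels to project (default: all
#'   available beyond baseline).
#' @param grid_mode `"reduced"` (desk scale) or `"full"` (reference
#'   lattices).
#' @param n_folds cross-validation folds (default 10).
#' @param max_step_km dispersal step limit, km.
#' @param min_sensitivity sensitivity bound of the minimum-training-area
#'   threshold.
#' @param seed integer master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @return an object of class `species_config`.
#' @export
species_config <- function(species_id, group, occurrences, world = NULL,
                           stacks = NULL, bathymetry = NULL,
                           predictors = NULL, monotone = NULL,
                           max_depth_m = Inf, scenarios = NULL,
                           grid_mode = c("reduced", "full"), n_folds = 10,
                           max_step_km = 200, min_sensitivity = 0.95,
                           seed = 1) {
  group <- match.arg(group, SPECIES_GROUPS)
  grid_mode <- match.arg(grid_mode)
  if (is.null(world) && is.null(stacks)) {
    stop("supply either a synthetic world or a list of predictor stacks",
         call. = FALSE)
  }
  if (is.null(stacks)) {
    scen_avail <- names(world$scenario_offsets)
    scenarios <- scenarios %||% scen_avail
    stacks <- c(list(baseline = world_stack(world, "baseline")),
                stats::setNames(lapply(scenarios, world_stack, world = world),
                                scenarios))
    bathymetry <- bathymetry %||% world_bathymetry(world)
  } else {
    scenarios <- scenarios %||% setdiff(names(stacks), "baseline")
    stacks <- stacks[c("baseline", scenarios)]
  }
  avail <- stack_names(stacks[["baseline"]])
  predictors <- predictors %||% intersect(group_predictors(group), avail)
  if (!length(predictors)) {
    stop("none of the group's predictors are available in the stack; ",
         "set `predictors` explicitly", call. = FALSE)
  }
  if (any(!predictors %in% avail)) {
    stop("predictor(s) not in the stack: ",
         paste(setdiff(predictors, avail), collapse = ", "), call. = FALSE)
  }
  monotone <- monotone %||% default_monotone_map()
  missing_dir <- setdiff(predictors, names(monotone))
  if (length(missing_dir)) {
    stop("no monotone direction for: ", paste(missing_dir, collapse = ", "),
         call. = FALSE)
  }
  # restrict every stack to the modelled predictors
  stacks <- lapply(stacks, function(st)
    predictor_stack(st$grids[predictors], scenario = st$scenario))
  structure(
    list(species_id = species_id, group = group, occurrences = occurrences,
         stacks = stacks, bathymetry = bathymetry, predictors = predictors,
         monotone = monotone, max_depth_m = max_depth_m,
         scenarios = scenarios, grid_mode = grid_mode, n_folds = n_folds,
         max_step_km = max_step_km, min_sensitivity = min_sensitivity,
         seed = as.integer(seed)),
    class = "species_config"
  )
}

#' @export
print.species_config <- function(x, ...) {
  cat(sprintf("<species_config> %s (%s); predictors: %s\n  scenarios: %s; grid %s; seed %d\n",
              x$species_id, x$group, paste(x$predictors, collapse = ", "),
              paste(x$scenarios, collapse = ", "), x$grid_mode, x$seed))
  invisible(x)
}
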