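# End-to-end per-species workflow: load -> thin at the estimated
# autocorrelation distance -> climatically structured pseudo-absences ->
# hexagon-block folds -> per-algorithm grid-search CV -> weighted ensemble
# -> metrics, contributions, tipping points -> thresholded, depth- and
# dispersal-clipped range maps per scenario -> run manifest.

stage_seed <- function(seed, stage) {
  offsets <- c(correlogram = 11L, thinning = 22L, pseudoabsence = 33L,
               folds = 44L, cv = 55L, contribution = 66L)
  seed + offsets[[stage]]
}

#' Run the full modelling workflow for one species
#'
#' @param config a [species_config()].
#' @param out_dir optional output directory; when given, range/uncertainty/
#'   suitability GeoTIFFs, CSV reports and a JSON manifest are written under
#'   `out_dir/<group>/<species>/`.
#' @param quiet suppress stage messages.
#' @return an object of class `run_manifest` (list): record counts, the
#'   autocorrelation distance, chosen hyperparameters, CV metrics, ensemble
#'   weights, threshold, tipping points, contributions, projected maps and
#'   output files.
#' @export
run_species <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "species_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()
  seed <- config$seed
  baseline <- config$stacks[["baseline"]]

  occ <- config$occurrences
  if (is.character(occ)) occ <- read_occurrences(occ, config$species_id)
  occ <- dplyr::distinct(normalize_lonlat(occ))
  say("[%s] %d occurrence records loaded", config$species_id, nrow(occ))

  cg <- estimate_autocorrelation_distance(baseline,
                                          seed = stage_seed(seed, "correlogram"))
  d_km <- uncorrelated_distance(cg)
  say("[%s] uncorrelated distance %.0f km", config$species_id, d_km)

  thinned <- thin_occurrences(occ, d_km, seed = stage_seed(seed, "thinning"))
  say("[%s] %d records after thinning", config$species_id, nrow(thinned))

  # exclusion buffer defaults to the uncorrelated distance; on small
  # domains it can exhaust the candidate pool, in which case it is halved
  # until enough candidates remain (floor: no buffer beyond the occupied
  # cells themselves)
  excl_km <- d_km
  repeat {
    runs <- tryCatch(
      generate_pseudoabsences(baseline, thinned, exclusion_km = excl_km,
                              seed = stage_seed(seed, "pseudoabsence")),
      error = function(e) {
        if (grepl("candidate pool", conditionMessage(e)) && excl_km > 0) e
        else stop(e)
      })
    if (!inherits(runs, "error")) break
    excl_km <- if (excl_km > 10) excl_km / 2 else 0
    say("[%s] pseudo-absence candidate pool too small; exclusion reduced to %.0f km",
        config$species_id, excl_km)
  }
  say("[%s] %d run(s), %d pseudo-absence(s) each (exclusion %.0f km)",
      config$species_id, length(runs), sum(runs[[1]]$label == 0), excl_km)

  # hexagon folds per run; add_hex_folds reduces the fold count when fewer
  # presence hexagons are occupied, and the hexagon width itself is halved
  # (at most 5 times) if presences span fewer than two hexagons
  train <- dplyr::bind_rows(runs)
  hex_km <- d_km
  for (attempt in 1:6) {
    folded <- tryCatch(
      withCallingHandlers(
        add_hex_folds(train, hex_width_km = hex_km,
                      n_folds = config$n_folds,
                      seed = stage_seed(seed, "folds")),
        message = function(m) {
          say("[%s] %s", config$species_id, trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        }),
      error = function(e) e)
    if (!inherits(folded, "error")) break
    if (attempt == 6) stop(folded)
    hex_km <- hex_km / 2
    say("[%s] presences span too few hexagons; hexagon width reduced to %.0f km",
        config$species_id, hex_km)
  }
  train <- folded
  n_folds <- max(train$fold)

  feats <- config$predictors
  coll <- collinearity(as.matrix(train[, feats, drop = FALSE]))

  cv_rows <- list(); models <- list()
  for (a in ALGORITHMS) {
    grid <- hyper_grid(a, config$grid_mode)
    per_run <- lapply(sort(unique(train$run)), function(r) {
      tr <- train[train$run == r, , drop = FALSE]
      cv <- cross_validate(tr, a, grid = grid, monotone_map = config$monotone,
                           seed = stage_seed(seed, "cv") + r,
                           min_sensitivity = config$min_sensitivity)
      final <- fit_model(tr, a, cv$best[names(grid)], config$monotone,
                         seed = stage_seed(seed, "cv") + r)
      list(cv = cv, model = final, run = r)
    })
    models[[a]] <- lapply(per_run, `[[`, "model")
    cv_rows[[a]] <- purrr::map_dfr(per_run, function(x)
      dplyr::mutate(x$cv$best, algorithm = a, run = x$run, .before = 1L))
    say("[%s] %s: mean CV AUC %.3f", config$species_id, a,
        mean(cv_rows[[a]]$auc))
  }
  cv_report <- dplyr::bind_rows(cv_rows)
  algo_metrics <- dplyr::summarise(
    dplyr::group_by(cv_report, .data$algorithm),
    dplyr::across(c("auc", "sensitivity", "specificity", "tss", "boyce"),
                  ~ mean(.x, na.rm = TRUE)), .groups = "drop")

  ensemble <- build_ensemble(models, algo_metrics, weight_metric = "auc",
                             max_depth_m = config$max_depth_m)
  pres <- train[train$label == 1L & train$run == train$run[1L], , drop = FALSE]
  pres_scores <- predict(ensemble, pres)
  base_suit <- ensemble_predict(ensemble, baseline)$suitability
  thr <- mtp_threshold(pres_scores, base_suit,
                       min_sensitivity = config$min_sensitivity)
  ensemble$threshold <- thr$threshold
  say("[%s] weights: %s; threshold %.3f (training sensitivity %.3f)",
      config$species_id,
      paste(sprintf("%s=%.2f", names(ensemble$weights), ensemble$weights),
            collapse = " "), thr$threshold, thr$sensitivity)

  # final-model evaluation: ensemble on the full training data, Boyce
  # against the baseline suitability map as background
  run1 <- train[train$run == train$run[1L], , drop = FALSE]
  ens_scores <- predict(ensemble, run1)
  fin_cm <- confusion_metrics(run1$label, ens_scores, thr$threshold)
  bg <- base_suit$values[!is.na(base_suit$values)]
  fin_boyce <- tryCatch(
    suppressWarnings(boyce_index(pres_scores, bg)),
    error = function(e) NA_real_)
  final_metrics <- dplyr::bind_cols(
    tibble::tibble(model = "ensemble", auc = sdm_auc(run1$label, ens_scores)),
    fin_cm, tibble::tibble(boyce = fin_boyce))

  contrib <- relative_contribution(ensemble, train,
                                   seed = stage_seed(seed, "contribution"))
  tp <- tipping_points(ensemble, train, monotone_map = config$monotone)

  maps <- project_scenarios(ensemble, config$stacks, occurrences = thinned,
                            bathymetry = config$bathymetry,
                            max_step_km = config$max_step_km)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir <- file.path(out_dir, gsub("[^A-Za-z0-9_-]", "_", config$group),
                     gsub("[^A-Za-z0-9_-]", "_", config$species_id))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sp <- gsub("[^A-Za-z0-9_-]", "_", config$species_id)
    for (sc in names(maps)) {
      for (layer in c("suitability", "uncertainty", "range")) {
        f <- file.path(dir, sprintf("%s_%s_%s.tif", sp, sc, layer))
        write_raster(maps[[sc]][[layer]], f)
        files <- c(files, f)
      }
    }
    reports <- list(metrics = cv_report, contributions = contrib,
                    tipping_points = tp, correlogram = tibble::as_tibble(cg))
    for (nm in names(reports)) {
      f <- file.path(dir, sprintf("%s_%s.csv", sp, nm))
      utils::write.csv(reports[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
  }

  manifest <- structure(list(
    species_id = config$species_id, group = config$group, seed = seed,
    n_occurrences = nrow(occ), n_thinned = nrow(thinned),
    n_runs = length(runs), n_pseudoabsences = sum(runs[[1]]$label == 0),
    n_folds = n_folds, uncorrelated_distance_km = d_km,
    grid_mode = config$grid_mode,
    hyperparameters = cv_report, cv_metrics = algo_metrics,
    final_metrics = final_metrics,
    weights = as.list(ensemble$weights), threshold = thr$threshold,
    training_sensitivity = thr$sensitivity,
    collinearity = coll, contributions = contrib, tipping_points = tp,
    correlogram = cg, training = train, ensemble = ensemble, maps = maps,
    range_area = purrr::map_dfr(names(maps), function(sc)
      dplyr::mutate(range_area(maps[[sc]]$range), scenario = sc, .before = 1L)),
    files = files,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "run_manifest")
  if (!is.null(out_dir)) {
    mf <- file.path(dirname(files[1]), paste0(
      gsub("[^A-Za-z0-9_-]", "_", config$species_id), "_manifest.json"))
    keep <- c("species_id", "group", "seed", "n_occurrences", "n_thinned",
              "n_runs", "n_pseudoabsences", "n_folds",
              "uncorrelated_distance_km", "grid_mode", "weights", "threshold",
              "training_sensitivity", "files", "elapsed_s")
    jsonlite::write_json(manifest[keep], mf, auto_unbox = TRUE, digits = NA)
    manifest$files <- c(manifest$files, mf)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "<run_manifest> %s (%s): %d occ -> %d thinned; %d run(s) x %d PA; threshold %.3f\n",
    x$species_id, x$group, x$n_occurrences, x$n_thinned, x$n_runs,
    x$n_pseudoabsences, x$threshold))
  cat(sprintf("  weights: %s; %0.f s\n",
              paste(sprintf("%s=%.2f", names(x$weights), unlist(x$weights)),
                    collapse = " "), x$elapsed_s))
  invisible(x)
}

#' Run a batch of species independently
#'
#' Failures are isolated per species; results are identical to sequential
#' execution given the same per-species seeds.
#'
#' @param configs list of [species_config()]s.
#' @param out_dir optional output directory passed to [run_species()].
#' @param quiet suppress stage messages.
#' @return list with one element per config: a `run_manifest`, or a
#'   `run_failure` record with the error message.
#' @export
run_batch <- function(configs, out_dir = NULL, quiet = FALSE) {
  if (!length(configs)) stop("no configs supplied", call. = FALSE)
  lapply(configs, function(cf) {
    tryCatch(run_species(cf, out_dir = out_dir, quiet = quiet),
             error = function(e) structure(
               list(species_id = cf$species_id, error = conditionMessage(e)),
               class = "run_failure"))
  })
}

#' @describeIn run_species tidy(): per-algorithm, per-run CV results.
#' @param x a `run_manifest`.
#' @param ... unused.
#' @export
tidy.run_manifest <- function(x, ...) x$hyperparameters

#' @describeIn run_species glance(): one-row run summary.
#' @export
glance.run_manifest <- function(x, ...) {
  tibble::tibble(species_id = x$species_id, group = x$group,
                 n_occurrences = x$n_occurrences, n_thinned = x$n_thinned,
                 n_runs = x$n_runs, n_pseudoabsences = x$n_pseudoabsences,
                 uncorrelated_distance_km = x$uncorrelated_distance_km,
                 threshold = x$threshold,
                 training_sensitivity = x$training_sensitivity,
                 mean_cv_auc = mean(x$cv_metrics$auc))
}

#' @describeIn cross_validate tidy(): per-fold metrics of the winning
#'   combination.
#' @param x an `sdm_cv`.
#' @param ... unused.
#' @export
tidy.sdm_cv <- function(x, ...) x$folds

#' @describeIn cross_validate glance(): the winning combination and its
#'   mean CV metrics.
#' @export
glance.sdm_cv <- function(x, ...) {
  dplyr::mutate(x$best, algorithm = x$algorithm, .before = 1L)
}
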