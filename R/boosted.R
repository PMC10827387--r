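# The three boosted-tree algorithms, all realized on the xgboost backend so
# per-predictor monotone constraints are enforceable uniformly:
#   brt      - depth-limited trees, logistic loss; axes: learning rate,
#              tree complexity (max depth), number of trees.
#   adaboost - leaf-limited trees, exponential (AdaBoost) loss via a custom
#              objective; axes: iterations, degrees of freedom (d splits =
#              d + 1 leaves), shrinkage. Probabilities via sigmoid(2 * margin).
#   xgb      - depth-limited trees, logistic loss with a minimum-gain
#              (gamma) axis; axes: gamma, interaction depth, shrinkage,
#              rounds.

ALGORITHMS <- c("brt", "adaboost", "xgb")

#' Hyperparameter grid for one algorithm
#'
#' `mode = "full"` reproduces the complete reference lattices (240 BRT, 240
#' AdaBoost, 1200 XGBoost combinations); `mode = "reduced"` is a small
#' 2-values-per-axis grid for desk-scale runs and tests.
#'
#' @param algorithm `"brt"`, `"adaboost"` or `"xgb"`.
#' @param mode `"full"` or `"reduced"`.
#' @return tibble, one row per hyperparameter combination, in deterministic
#'   column-major order.
#' @export
hyper_grid <- function(algorithm, mode = c("full", "reduced")) {
  mode <- match.arg(mode)
  grids <- if (mode == "full") {
    list(
      brt = expand.grid(learning_rate = c(0.1, 0.01, 0.001),
                        tree_complexity = 1:4,
                        n_trees = seq(50L, 1000L, by = 50L)),
      adaboost = expand.grid(n_iterations = seq(50L, 250L, by = 50L),
                             degrees_freedom = 1:12,
                             shrinkage = seq(0.25, 1, by = 0.25)),
      xgb = expand.grid(gamma = 0:5, interaction_depth = 1:4,
                        shrinkage = seq(0.1, 0.5, by = 0.1),
                        n_rounds = seq(10L, 100L, by = 10L))
    )
  } else {
    list(
      brt = expand.grid(learning_rate = c(0.1, 0.01),
                        tree_complexity = c(2L, 3L),
                        n_trees = c(50L, 100L)),
      adaboost = expand.grid(n_iterations = c(50L, 100L),
                             degrees_freedom = c(2L, 8L),
                             shrinkage = c(0.5, 1)),
      xgb = expand.grid(gamma = c(0, 1), interaction_depth = c(2L, 3L),
                        shrinkage = c(0.1, 0.3), n_rounds = c(20L, 50L))
    )
  }
  if (!algorithm %in% names(grids)) {
    stop("unknown algorithm '", algorithm, "'; known: ",
         paste(ALGORITHMS, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(grids[[algorithm]])
}

#' Enumerate the full reference hyperparameter lattice
#'
#' @param algorithm `"brt"`, `"adaboost"` or `"xgb"`.
#' @return tibble of all combinations (Cartesian product, deterministic
#'   order).
#' @export
enumerate_grid <- function(algorithm) hyper_grid(algorithm, mode = "full")

#' Default monotone directions by predictor
#'
#' Maximum temperature, sea ice cover, wave energy and sea water speed are
#' constrained to affect suitability negatively; minimum temperature,
#' salinity, nutrients, pH, oxygen, productivity, terrain slope and
#' ruggedness positively.
#'
#' @return named integer vector of +1/-1 directions.
#' @export
default_monotone_map <- function() {
  c(temp_max = -1L, sea_ice = -1L, wave_energy = -1L, water_speed = -1L,
    temp_min = 1L, salinity = 1L, nitrate = 1L, ph = 1L, oxygen = 1L,
    phytoplankton = 1L, slope = 1L, ruggedness = 1L)
}

training_features <- function(train) {
  setdiff(names(train), c("run", "lon", "lat", "label", "fold", "cluster"))
}

adaboost_objective <- function(preds, dtrain) {
  y <- 2 * xgboost::getinfo(dtrain, "label") - 1
  e <- exp(pmin(-y * preds, 30))   # clamp to keep the hessian finite
  list(grad = -y * e, hess = e)
}

#' Fit one monotone-constrained boosted-tree model
#'
#' @param train training tibble with a 0/1 `label` column and one column
#'   per predictor (coordinate/bookkeeping columns are ignored).
#' @param algorithm `"brt"`, `"adaboost"` or `"xgb"`.
#' @param hyperparams one-row data frame or named list from the algorithm's
#'   [hyper_grid()]. Values outside the reference lattice are allowed with
#'   a warning.
#' @param monotone_map named vector of +1/-1 directions; every predictor in
#'   the training set must have a direction (see [default_monotone_map()]).
#' @param seed integer seed (fits are deterministic given data, parameters
#'   and seed).
#' @return an object of class `sdm_model`; `predict()` returns
#'   probabilities in `[0, 1]`.
#' @export
fit_model <- function(train, algorithm, hyperparams,
                      monotone_map = default_monotone_map(), seed = 1) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  hp <- as.list(hyperparams)
  feats <- training_features(train)
  if (!length(feats)) stop("no predictor columns in training set", call. = FALSE)
  y <- as.integer(train$label)
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- as.matrix(train[, feats, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  missing_dir <- setdiff(feats, names(monotone_map))
  if (length(missing_dir)) {
    stop("no monotone direction for predictor(s): ",
         paste(missing_dir, collapse = ", "), call. = FALSE)
  }
  mono <- as.integer(monotone_map[feats])
  full <- hyper_grid(algorithm, "full")
  need_hp <- setdiff(names(full), names(hp))
  if (length(need_hp)) {
    stop("missing ", algorithm, " hyperparameter(s): ",
         paste(need_hp, collapse = ", "), call. = FALSE)
  }
  hp <- hp[names(full)]
  # the full grid is a Cartesian product, so per-axis membership suffices
  on_lattice <- all(vapply(names(hp), function(nm)
    any(abs(as.numeric(hp[[nm]]) - unique(as.numeric(full[[nm]]))) < 1e-9),
    logical(1)))
  if (!on_lattice) {
    warning("hyperparameters outside the reference ", algorithm, " lattice")
  }

  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  common <- list(monotone_constraints = mono, nthread = 1, seed = seed)
  booster <- withr::with_seed(seed, switch(
    algorithm,
    brt = xgboost::xgb.train(
      params = c(list(objective = "binary:logistic",
                      eta = hp$learning_rate,
                      max_depth = as.integer(hp$tree_complexity)), common),
      data = dtrain, nrounds = as.integer(hp$n_trees), verbose = 0),
    adaboost = xgboost::xgb.train(
      params = c(list(eta = hp$shrinkage, max_depth = 0L,
                      max_leaves = as.integer(hp$degrees_freedom) + 1L,
                      grow_policy = "lossguide", tree_method = "hist",
                      base_score = 0), common),
      data = dtrain, nrounds = as.integer(hp$n_iterations),
      obj = adaboost_objective, verbose = 0),
    xgb = xgboost::xgb.train(
      params = c(list(objective = "binary:logistic",
                      gamma = hp$gamma,
                      eta = hp$shrinkage,
                      max_depth = as.integer(hp$interaction_depth)), common),
      data = dtrain, nrounds = as.integer(hp$n_rounds), verbose = 0)
  ))
  structure(
    list(algorithm = algorithm, hyperparams = tibble::as_tibble(hp),
         booster = booster, features = feats,
         monotone = stats::setNames(mono, feats), seed = seed,
         n_presence = sum(y == 1L), n_absence = sum(y == 0L)),
    class = "sdm_model"
  )
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %s (%d presences / %d pseudo-absences)\n",
              x$algorithm, x$n_presence, x$n_absence))
  cat("  ", paste(names(x$hyperparams), unlist(x$hyperparams),
                  sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict suitability from a fitted model
#'
#' @param object an `sdm_model`.
#' @param newdata data frame or matrix containing the model's feature
#'   columns.
#' @param ... unused.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  dm <- xgboost::xgb.DMatrix(X, nthread = 1)
  p <- predict(object$booster, dm)
  if (object$algorithm == "adaboost") p <- stats::plogis(2 * p)
  pmin(pmax(p, 0), 1)
}

#' Grid-search spatial cross-validation for one algorithm
#'
#' For every hyperparameter combination, fits on all folds but one and
#' evaluates on the held-out fold (AUC; sensitivity/specificity/TSS at the
#' minimum-training-area threshold computed on the training-fold presences;
#' Boyce where the fold is large enough). The winner has the highest mean
#' CV AUC, ties broken by higher mean Boyce, then by fewer boosting
#' iterations (parsimony).
#'
#' @param train training tibble with `label`, `fold` and predictor columns.
#' @param algorithm `"brt"`, `"adaboost"` or `"xgb"`.
#' @param grid hyperparameter tibble (default the algorithm's reduced grid).
#' @param monotone_map named +1/-1 directions.
#' @param seed integer seed.
#' @param min_sensitivity sensitivity bound for the fold-level threshold.
#' @return object of class `sdm_cv`: list with `best` (one-row tibble),
#'   `folds` (per-combination, per-fold metrics), `summary` (per-combination
#'   means) and `algorithm`.
#' @export
cross_validate <- function(train, algorithm, grid = NULL,
                           monotone_map = default_monotone_map(), seed = 1,
                           min_sensitivity = 0.95) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (is.null(grid)) grid <- hyper_grid(algorithm, "reduced")
  if (!"fold" %in% names(train)) stop("training set has no fold column", call. = FALSE)
  folds <- sort(unique(train$fold))
  if (length(folds) < 2L) stop("need >= 2 folds", call. = FALSE)
  pres_per_fold <- tapply(train$label, train$fold, function(l) sum(l == 1L))
  if (any(pres_per_fold == 0L)) {
    stop("fold(s) without presences: ",
         paste(names(pres_per_fold)[pres_per_fold == 0L], collapse = ", "),
         "; re-tessellate or merge folds", call. = FALSE)
  }

  fold_rows <- purrr::map_dfr(seq_len(nrow(grid)), function(gi) {
    hp <- grid[gi, , drop = FALSE]
    purrr::map_dfr(folds, function(f) {
      tr <- train[train$fold != f, , drop = FALSE]
      te <- train[train$fold == f, , drop = FALSE]
      if (length(unique(tr$label)) < 2L || length(unique(te$label)) < 2L) {
        return(tibble::tibble(combo = gi, fold = f, auc = NA_real_,
                              sensitivity = NA_real_, specificity = NA_real_,
                              tss = NA_real_, boyce = NA_real_))
      }
      m <- fit_model(tr, algorithm, hp, monotone_map, seed = seed)
      p_te <- predict(m, te)
      thr <- mtp_threshold(predict(m, tr[tr$label == 1L, , drop = FALSE]),
                           min_sensitivity = min_sensitivity)$threshold
      cm <- confusion_metrics(te$label, p_te, thr)
      by <- tryCatch(
        suppressWarnings(boyce_index(p_te[te$label == 1L], p_te)),
        error = function(e) NA_real_)
      tibble::tibble(combo = gi, fold = f, auc = sdm_auc(te$label, p_te),
                     sensitivity = cm$sensitivity,
                     specificity = cm$specificity, tss = cm$tss, boyce = by)
    })
  })

  summary <- dplyr::summarise(
    dplyr::group_by(fold_rows, .data$combo),
    dplyr::across(c("auc", "sensitivity", "specificity", "tss", "boyce"),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  iter_col <- intersect(c("n_trees", "n_iterations", "n_rounds"), names(grid))
  parsimony <- as.numeric(grid[[iter_col]])
  boyce0 <- ifelse(is.finite(summary$boyce), summary$boyce, 0)
  best_i <- order(-round(summary$auc, 10), -round(boyce0, 10), parsimony)[1L]
  structure(
    list(algorithm = algorithm,
         best = dplyr::bind_cols(grid[best_i, , drop = FALSE],
                                 summary[best_i, -1L]),
         folds = fold_rows[fold_rows$combo == best_i, , drop = FALSE],
         all_folds = fold_rows, summary = dplyr::bind_cols(grid, summary[-1L]),
         seed = seed),
    class = "sdm_cv"
  )
}

#' @export
print.sdm_cv <- function(x, ...) {
  cat(sprintf("<sdm_cv> %s: best mean AUC %.3f over %d folds\n",
              x$algorithm, x$best$auc, length(unique(x$folds$fold))))
  invisible(x)
}

#' Predict a suitability map over a predictor stack
#'
#' @param model an `sdm_model` (or `sdm_ensemble`, see
#'   [ensemble_predict()]).
#' @param stack a [predictor_stack()] providing every feature the model
#'   uses.
#' @return a suitability [raster_grid()] in `[0, 1]`; masked cells stay
#'   nodata.
#' @export
predict_map <- function(model, stack) {
  stopifnot(inherits(stack, "predictor_stack"))
  missing <- setdiff(model$features, stack_names(stack))
  if (length(missing)) {
    stop("stack is missing predictor layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref <- stack_ref_grid(stack)
  cells <- unmasked_cells(ref)
  out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  if (length(cells)) {
    X <- vapply(model$features, function(nm) stack$grids[[nm]]$values[cells],
                numeric(length(cells)))
    if (length(cells) == 1L) X <- matrix(X, nrow = 1L,
                                         dimnames = list(NULL, model$features))
    out[cells] <- predict(model, as.data.frame(X))
  }
  raster_grid(out, west = ref$west, north = ref$north, cell = ref$cell)
}
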