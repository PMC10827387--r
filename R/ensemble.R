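# Weighted-average ensemble of the three algorithms. Weights are
# proportional to cross-validated skill above a random-skill floor (0.5 for
# AUC, 0 for Boyce); per-cell uncertainty is the sample standard deviation
# across the per-algorithm maps (runs averaged within algorithm first).

#' Build a weighted-average ensemble from fitted members
#'
#' @param models list of `sdm_model` members, or a list of lists for
#'   multiple runs per algorithm.
#' @param metrics named numeric vector or tibble giving each algorithm's
#'   cross-validated skill (names/column `algorithm`, value/column given by
#'   `weight_metric`).
#' @param weight_metric `"auc"` (floor 0.5) or `"boyce"` (floor 0).
#' @param threshold minimum-training-area threshold to attach (may be set
#'   later by [project_scenarios()]).
#' @param max_depth_m species' maximum known depth for depth clipping.
#' @return an object of class `sdm_ensemble`: members (tibble of
#'   algorithm/run/model), normalized per-algorithm `weights`, `threshold`,
#'   `max_depth_m`.
#' @export
build_ensemble <- function(models, metrics, weight_metric = c("auc", "boyce"),
                           threshold = NA_real_, max_depth_m = Inf) {
  weight_metric <- match.arg(weight_metric)
  if (!length(models)) stop("empty model list", call. = FALSE)
  flat <- list(); algo <- character(0); run <- integer(0)
  add <- function(m, r) {
    flat[[length(flat) + 1L]] <<- m
    algo <<- c(algo, m$algorithm); run <<- c(run, r)
  }
  for (el in models) {
    if (inherits(el, "sdm_model")) add(el, 1L)
    else for (r in seq_along(el)) add(el[[r]], r)
  }
  members <- tibble::tibble(algorithm = algo, run = run, model = flat)
  feats <- unique(unlist(lapply(flat, `[[`, "features")))
  same <- vapply(flat, function(m) setequal(m$features, feats), logical(1))
  if (!all(same)) stop("ensemble members must share one predictor set", call. = FALSE)

  if (is.data.frame(metrics)) {
    mv <- stats::setNames(metrics[[weight_metric]], metrics$algorithm)
  } else {
    mv <- metrics
  }
  algos <- unique(members$algorithm)
  missing <- setdiff(algos, names(mv))
  if (length(missing)) {
    stop("no ", weight_metric, " metric for algorithm(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  floor_v <- if (weight_metric == "auc") 0.5 else 0
  w <- pmax(as.numeric(mv[algos]) - floor_v, 0)
  if (sum(w) == 0) {
    warning("all ensemble weights zero after flooring; using equal weights")
    w <- rep(1, length(algos))
  }
  w <- w / sum(w)
  structure(
    list(members = members, weights = stats::setNames(w, algos),
         weight_metric = weight_metric, metric_values = mv[algos],
         threshold = threshold, max_depth_m = max_depth_m,
         features = feats),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %d member(s); weights: %s; threshold %s\n",
              nrow(x$members),
              paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                    collapse = ", "),
              ifelse(is.na(x$threshold), "unset", format(x$threshold))))
  invisible(x)
}

#' Predict pointwise suitability from an ensemble
#'
#' @param object an `sdm_ensemble`.
#' @param newdata data frame with the ensemble's feature columns.
#' @param ... unused.
#' @return weighted-mean suitability in `[0, 1]`.
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  algos <- names(object$weights)
  per_algo <- vapply(algos, function(a) {
    ms <- object$members$model[object$members$algorithm == a]
    rowMeans(vapply(ms, function(m) predict(m, newdata),
                    numeric(nrow(as.data.frame(newdata)))))
  }, numeric(nrow(as.data.frame(newdata))))
  as.numeric(per_algo %*% object$weights[algos])
}

#' Ensemble suitability and uncertainty maps
#'
#' Suitability is the weighted mean of the per-algorithm maps (member runs
#' averaged within algorithm first); uncertainty is the unweighted sample
#' standard deviation (n - 1) across the per-algorithm maps, zero wherever
#' members agree exactly, and 0 by convention for a single-member ensemble.
#'
#' @param ensemble an `sdm_ensemble`.
#' @param stack a [predictor_stack()] covering the ensemble's predictors.
#' @return list with `suitability` and `uncertainty` [raster_grid()]s.
#' @export
ensemble_predict <- function(ensemble, stack) {
  stopifnot(inherits(ensemble, "sdm_ensemble"))
  algos <- names(ensemble$weights)
  maps <- lapply(algos, function(a) {
    ms <- ensemble$members$model[ensemble$members$algorithm == a]
    vals <- lapply(ms, function(m) predict_map(m, stack)$values)
    Reduce(`+`, vals) / length(vals)
  })
  ref <- stack_ref_grid(stack)
  arr <- array(unlist(maps), dim = c(nrow(ref$values), ncol(ref$values),
                                     length(maps)))
  suit <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (k in seq_along(algos)) {
    suit <- suit + ensemble$weights[[algos[k]]] * arr[, , k]
  }
  unc <- if (length(maps) >= 2L) apply(arr, c(1, 2), stats::sd)
         else matrix(0, nrow(ref$values), ncol(ref$values))
  unc[is.na(suit)] <- NA_real_
  list(
    suitability = raster_grid(suit, ref$west, ref$north, ref$cell),
    uncertainty = raster_grid(unc, ref$west, ref$north, ref$cell)
  )
}

#' @describeIn build_ensemble tidy(): one row per member with its weight.
#' @param x an `sdm_ensemble`.
#' @param ... unused.
#' @export
tidy.sdm_ensemble <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$members, "algorithm", "run"),
    weight = as.numeric(x$weights[.data$algorithm]),
    metric = as.numeric(x$metric_values[.data$algorithm]),
    hyperparams = purrr::map(x$members$model, "hyperparams"))
}

#' @describeIn build_ensemble glance(): one-row summary.
#' @export
glance.sdm_ensemble <- function(x, ...) {
  tibble::tibble(n_members = nrow(x$members),
                 n_algorithms = length(x$weights),
                 weight_metric = x$weight_metric,
                 threshold = x$threshold,
                 max_depth_m = x$max_depth_m)
}
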