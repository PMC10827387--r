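# Model interpretation: permutation-based relative contributions (so the
# three algorithms and the ensemble are scored identically), partial
# dependence curves, and extraction of hypothetical physiological tolerance
# limits ("tipping points") as the partial-dependence crossing of a
# suitability threshold, on the side dictated by the predictor's monotone
# direction.

#' Relative contribution of predictors (%)
#'
#' Permutation importance per member model: the mean drop in training AUC
#' over `n_permutations` shuffles of each predictor column, floored at 0
#' and normalized to sum to 100%. The ensemble column is the weight-averaged
#' member contribution, re-normalized to 100%.
#'
#' @param ensemble an `sdm_ensemble` (or a single `sdm_model`).
#' @param train training tibble with `label` and predictor columns; with
#'   multiple runs (a `run` column), each member is scored on its own run's
#'   rows.
#' @param n_permutations shuffles per predictor (>= 1).
#' @param seed integer seed.
#' @return tibble: `predictor`, one column per algorithm, `ensemble`; every
#'   numeric column sums to 100.
#' @export
relative_contribution <- function(ensemble, train, n_permutations = 3,
                                  seed = 1) {
  if (inherits(ensemble, "sdm_model")) {
    ensemble <- build_ensemble(list(ensemble),
                               stats::setNames(1, ensemble$algorithm))
  }
  stopifnot(inherits(ensemble, "sdm_ensemble"))
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  feats <- ensemble$features
  if (!"run" %in% names(train)) train$run <- 1L

  member_drop <- function(model, rows, perm_seed) {
    y <- rows$label
    if (length(unique(y)) < 2L) stop("single-class training rows", call. = FALSE)
    base_auc <- sdm_auc(y, predict(model, rows))
    withr::with_seed(perm_seed, {
      vapply(feats, function(f) {
        drops <- vapply(seq_len(n_permutations), function(k) {
          shuffled <- rows
          shuffled[[f]] <- sample(shuffled[[f]])
          base_auc - sdm_auc(y, predict(model, shuffled))
        }, numeric(1))
        max(mean(drops), 0)
      }, numeric(1))
    })
  }

  members <- ensemble$members
  raw <- purrr::map(seq_len(nrow(members)), function(i) {
    rows <- train[train$run == members$run[i], , drop = FALSE]
    if (!nrow(rows)) rows <- train
    member_drop(members$model[[i]], rows, seed + i)
  })
  to_pct <- function(v) if (sum(v) == 0) rep(100 / length(v), length(v))
                        else 100 * v / sum(v)
  algos <- unique(members$algorithm)
  out <- tibble::tibble(predictor = feats)
  algo_pct <- list()
  for (a in algos) {
    idx <- which(members$algorithm == a)
    pct <- to_pct(rowMeans(vapply(raw[idx], identity,
                                  numeric(length(feats)))))
    algo_pct[[a]] <- pct
    out[[a]] <- pct
  }
  ens <- Reduce(`+`, purrr::map(algos, function(a)
    ensemble$weights[[a]] * algo_pct[[a]]))
  out$ensemble <- to_pct(ens)
  out
}

#' Partial-dependence curve of one predictor
#'
#' Values over an `n_grid`-point grid spanning the predictor's training
#' range; the value at grid point g is the mean prediction over the
#' training rows with the predictor column replaced by g (rows subsampled
#' to at most `max_rows` for speed).
#'
#' @param model an `sdm_model` or `sdm_ensemble`.
#' @param train training tibble with the predictor columns.
#' @param predictor predictor name.
#' @param n_grid number of grid points (>= 10).
#' @param max_rows row subsample cap.
#' @param seed seed for the row subsample.
#' @return tibble of class `sdm_pd` with `value` (predictor units,
#'   strictly increasing) and `suitability`.
#' @export
partial_dependence <- function(model, train, predictor, n_grid = 100,
                               max_rows = 2000, seed = 1) {
  feats <- if (inherits(model, "sdm_ensemble")) model$features
           else model$features
  if (!predictor %in% feats) {
    stop("predictor '", predictor, "' not in the model's feature set",
         call. = FALSE)
  }
  if (n_grid < 10) stop("n_grid must be >= 10", call. = FALSE)
  x <- train[[predictor]]
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) stop("zero-variance predictor '", predictor, "'",
                           call. = FALSE)
  rows <- train
  if (nrow(rows) > max_rows) {
    rows <- withr::with_seed(seed, rows[sample.int(nrow(rows), max_rows), ])
  }
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  suit <- vapply(grid, function(g) {
    rows[[predictor]] <- g
    mean(predict(model, rows))
  }, numeric(1))
  structure(tibble::tibble(value = grid, suitability = suit),
            class = c("sdm_pd", class(tibble::tibble())),
            predictor = predictor)
}

#' Extract a tolerance limit (tipping point) from a partial-dependence
#' curve
#'
#' For a negatively constrained predictor (direction -1) the limit is the
#' largest grid value where the curve stays at or above the threshold
#' (maximum tolerated level, side `"max"`); for direction +1 the smallest
#' such value (minimum requirement, side `"min"`). When the curve never
#' drops below the threshold the grid edge is returned flagged
#' `"unbounded in range"`; a curve entirely below the threshold yields an
#' `NA` limit flagged `"absent"`.
#'
#' @param pd an `sdm_pd` tibble from [partial_dependence()].
#' @param direction +1 or -1 monotone direction of the predictor.
#' @param suitability_threshold threshold in (0, 1); conventionally the
#'   species' minimum-training-area threshold.
#' @return tibble with `predictor`, `value`, `side`, `flag`.
#' @export
extract_tipping_point <- function(pd, direction, suitability_threshold) {
  stopifnot(direction %in% c(-1, 1))
  if (suitability_threshold <= 0 || suitability_threshold >= 1) {
    stop("suitability_threshold must be in (0, 1)", call. = FALSE)
  }
  side <- if (direction < 0) "max" else "min"
  above <- pd$suitability >= suitability_threshold
  if (!any(above)) {
    return(tibble::tibble(predictor = attr(pd, "predictor"),
                          value = NA_real_, side = side, flag = "absent"))
  }
  value <- if (direction < 0) max(pd$value[above]) else min(pd$value[above])
  at_edge <- (direction < 0 && value == max(pd$value)) ||
    (direction > 0 && value == min(pd$value))
  tibble::tibble(predictor = attr(pd, "predictor"), value = value,
                 side = side,
                 flag = if (all(above) || at_edge) "unbounded in range"
                        else "crossing")
}

#' Tipping points for every constrained predictor of an ensemble
#'
#' The operational rule: a tolerance limit is the predictor value at which
#' the species' response effectively vanishes, so each limit is read where
#' the partial-dependence curve crosses a small fraction
#' (`level_fraction`, default 0.1) of the curve's own maximum. Two scales
#' that do not transfer are deliberately avoided: the absolute
#' minimum-training-area threshold usually exceeds the whole curve (a
#' partial-dependence curve averages over rows other predictors render
#' unsuitable, so its ceiling is well below the threshold computed on full
#' predictions), and a *high* relative level reads the top of the fitted
#' response drop, biasing the limit toward the niche optimum. Pass an
#' absolute `suitability_threshold` to override the rule entirely (e.g.
#' the MTP threshold itself).
#'
#' @param ensemble an `sdm_ensemble`.
#' @param train training tibble.
#' @param monotone_map named +1/-1 directions.
#' @param level_fraction detection level as a fraction of the curve
#'   maximum, in (0, 1).
#' @param suitability_threshold optional absolute crossing level in (0, 1);
#'   overrides `level_fraction`.
#' @param n_grid partial-dependence grid size.
#' @return tibble: one row per predictor with `value`, `side`, `flag`.
#' @export
tipping_points <- function(ensemble, train,
                           monotone_map = default_monotone_map(),
                           level_fraction = 0.1,
                           suitability_threshold = NULL, n_grid = 100) {
  if (level_fraction <= 0 || level_fraction >= 1) {
    stop("level_fraction must be in (0, 1)", call. = FALSE)
  }
  purrr::map_dfr(ensemble$features, function(f) {
    pd <- partial_dependence(ensemble, train, f, n_grid = n_grid)
    thr_f <- suitability_threshold %||%
      (level_fraction * max(pd$suitability))
    thr_f <- min(max(thr_f, 1e-6), 1 - 1e-6)
    extract_tipping_point(pd, direction = monotone_map[[f]],
                          suitability_threshold = thr_f)
  })
}

#' Plot a partial-dependence curve
#'
#' @param object an `sdm_pd` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sdm_pd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$suitability)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "predictor"), y = "Suitability") +
    ggplot2::ylim(0, 1)
}
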