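# Presence-only and threshold-based evaluation metrics. AUC is delegated to
# pROC (rank-based, ties counted 1/2); the continuous Boyce index, the
# minimum-training-area threshold and the collinearity diagnostics are
# implemented here.

#' Area under the ROC curve
#'
#' Probability that a randomly chosen presence outscores a randomly chosen
#' absence, ties counted one half (computed by pROC).
#'
#' @param labels 0/1 vector (1 = presence); both classes must be present.
#' @param scores numeric prediction scores.
#' @return AUC in `[0, 1]`.
#' @export
sdm_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = as.numeric(scores),
                                 levels = c(0L, 1L), direction = "<",
                                 quiet = TRUE)))
}

#' Sensitivity, specificity and TSS at a threshold
#'
#' Presence rule is `score >= threshold` (ties predicted present).
#'
#' @param labels 0/1 vector; both classes required.
#' @param scores numeric scores.
#' @param threshold classification threshold.
#' @return tibble with `sensitivity`, `specificity`, `tss`
#'   (TSS = sensitivity + specificity - 1).
#' @export
confusion_metrics <- function(labels, scores, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("confusion metrics need both classes present", call. = FALSE)
  }
  pred <- as.numeric(scores) >= threshold
  sens <- sum(pred & labels == 1L) / sum(labels == 1L)
  spec <- sum(!pred & labels == 0L) / sum(labels == 0L)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 tss = sens + spec - 1)
}

#' Continuous Boyce index
#'
#' Overlapping windows of width `window_fraction` times the background score
#' range slide over the background range; per window the
#' predicted-to-expected ratio P/E = (fraction of presence scores in the
#' window) / (fraction of background scores in the window) is computed
#' (windows with zero expected fraction are skipped), and the index is the
#' Spearman rank correlation between P/E and the window midpoints. Returns 0
#' with a warning when P/E is constant (correlation undefined).
#'
#' @param presence_scores scores at presence sites (>= 20 values).
#' @param background_scores scores over the background/environment
#'   (>= 100 values).
#' @param n_windows number of overlapping windows.
#' @param window_fraction window width as a fraction of the background
#'   score range.
#' @return Boyce index in `[-1, 1]`.
#' @export
boyce_index <- function(presence_scores, background_scores,
                        n_windows = 101, window_fraction = 0.1) {
  p <- as.numeric(presence_scores); b <- as.numeric(background_scores)
  p <- p[!is.na(p)]; b <- b[!is.na(b)]
  if (length(p) < 20L) stop("need >= 20 presence scores", call. = FALSE)
  if (length(b) < 100L) stop("need >= 100 background scores", call. = FALSE)
  rng <- range(b)
  if (diff(rng) == 0) {
    warning("constant background scores; Boyce undefined, returning 0")
    return(0)
  }
  width <- window_fraction * diff(rng)
  starts <- seq(rng[1L], rng[2L] - width, length.out = n_windows)
  mids <- starts + width / 2
  pe <- vapply(starts, function(s) {
    e <- mean(b >= s & b <= s + width)
    if (e == 0) return(NA_real_)
    mean(p >= s & p <= s + width) / e
  }, numeric(1))
  ok <- which(!is.na(pe))
  # overlapping windows produce runs of identical P/E; keep the first of
  # each run so artificial ties do not depress the rank correlation
  keep <- ok[c(TRUE, diff(pe[ok]) != 0)]
  if (length(keep) < 2L || stats::sd(pe[keep]) == 0) {
    warning("constant P/E ratio; Boyce undefined, returning 0")
    return(0)
  }
  suppressWarnings(stats::cor(pe[keep], mids[keep], method = "spearman"))
}

#' Minimum-training-area reclassification threshold
#'
#' The largest threshold `t` such that the fraction of training presence
#' scores at or above `t` is at least `min_sensitivity`; maximizing `t`
#' minimizes the predicted area. Optionally reports the predicted-area
#' fraction on a suitability map.
#'
#' @param presence_scores suitability scores at the training presences.
#' @param suitability_map optional [raster_grid()] to report the
#'   predicted-area fraction on.
#' @param min_sensitivity required training sensitivity in `(0, 1]`
#'   (default 0.95).
#' @return tibble with `threshold`, `sensitivity` (achieved on the training
#'   presences) and `area_fraction` (NA without a map).
#' @export
mtp_threshold <- function(presence_scores, suitability_map = NULL,
                          min_sensitivity = 0.95) {
  s <- as.numeric(presence_scores)
  s <- s[!is.na(s)]
  if (!length(s)) stop("no presence scores supplied", call. = FALSE)
  if (min_sensitivity <= 0 || min_sensitivity > 1) {
    stop("min_sensitivity must be in (0, 1]", call. = FALSE)
  }
  n <- length(s)
  m <- ceiling(min_sensitivity * n)        # presences that must stay present
  thr <- sort(s, decreasing = TRUE)[m]     # m-th largest score
  achieved <- mean(s >= thr)
  area <- NA_real_
  if (!is.null(suitability_map)) {
    v <- suitability_map$values
    area <- mean(v[!is.na(v)] >= thr)
  }
  tibble::tibble(threshold = thr, sensitivity = achieved, area_fraction = area)
}

#' Predictor collinearity: pairwise Pearson r and VIF
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on all others (on
#' the training feature matrix). Zero-variance predictors are flagged with
#' `NA`; perfectly collinear predictors get `Inf`.
#'
#' @param feature_matrix numeric matrix or data frame, >= 2 columns,
#'   >= 3 rows.
#' @return list with `r` (correlation matrix, unit diagonal) and `vif`
#'   (named vector).
#' @export
collinearity <- function(feature_matrix) {
  X <- as.matrix(feature_matrix)
  if (ncol(X) < 2L) stop("need >= 2 predictors", call. = FALSE)
  if (nrow(X) < 3L) stop("need >= 3 rows", call. = FALSE)
  if (any(!is.finite(X))) stop("feature matrix must be finite", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  vif <- vapply(seq_len(ncol(X)), function(j) {
    if (sds[j] == 0) return(NA_real_)
    others <- X[, -j, drop = FALSE]
    others <- others[, apply(others, 2L, stats::sd) > 0, drop = FALSE]
    if (!ncol(others)) return(1)
    fit <- stats::lm.fit(cbind(1, others), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  list(r = r, vif = vif)
}
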