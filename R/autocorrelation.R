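# Spatial autocorrelation of the predictor fields, estimated as a
# correlogram: Pearson correlation between predictor values at random site
# pairs, binned by great-circle distance. The lower edge of the first
# non-significant distance class is the "uncorrelated distance" used both to
# thin occurrences and to size the cross-validation hexagons.

#' Estimate the spatial autocorrelation distance of a predictor stack
#'
#' Samples random unmasked cell pairs, bins them by great-circle distance,
#' and per distance class computes the pooled Pearson correlation between
#' the two sites' standardized predictor values. A class is "significant"
#' when r > 0 and its two-sided p-value (at the class's site-pair count) is
#' below `alpha`. The uncorrelated distance is the lower edge of the first
#' non-significant class (falling back to `max_distance_km` when every class
#' is significant). Zero-variance predictors are excluded from pooling;
#' classes with fewer than 30 pairs are treated as non-significant.
#'
#' @param stack a [predictor_stack()].
#' @param n_pairs number of site pairs to sample (>= 1000).
#' @param class_width_km width of the distance classes, km.
#' @param max_distance_km largest distance considered, km.
#' @param alpha significance level for the per-class correlation test.
#' @param seed integer seed.
#' @return an object of class `correlogram`: a tibble with one row per
#'   distance class (`lower_km`, `upper_km`, `r`, `n_pairs`, `p_value`,
#'   `significant`) and attribute `uncorrelated_distance_km`.
#' @export
estimate_autocorrelation_distance <- function(stack, n_pairs = 10000,
                                              class_width_km = 50,
                                              max_distance_km = 600,
                                              alpha = 0.05, seed = 1) {
  stopifnot(inherits(stack, "predictor_stack"))
  if (n_pairs < 1000) stop("n_pairs must be >= 1000", call. = FALSE)
  ref <- stack_ref_grid(stack)
  cells <- unmasked_cells(ref)
  if (length(cells) < 10L) stop("too few unmasked cells", call. = FALSE)
  cc <- cell_centers(ref, cells)

  feats <- vapply(stack$grids, function(g) g$values[cells],
                  numeric(length(cells)))
  sds <- apply(feats, 2L, stats::sd)
  keep_pred <- !is.na(sds) & sds > 0
  if (!any(keep_pred)) {
    # all predictors constant: correlation undefined everywhere -> treat as
    # uncorrelated at the first class edge
    warning("all predictors have zero variance; treating world as uncorrelated")
  }
  feats <- scale(feats[, keep_pred, drop = FALSE])

  pairs <- withr::with_seed(seed, {
    i <- integer(0); j <- integer(0); d <- numeric(0)
    tries <- 0L
    while (length(i) < n_pairs && tries < 50L) {
      m <- max(2L * n_pairs, 2000L)
      a <- sample.int(length(cells), m, replace = TRUE)
      b <- sample.int(length(cells), m, replace = TRUE)
      dd <- great_circle_km(cbind(cc$lon[a], cc$lat[a]),
                            cbind(cc$lon[b], cc$lat[b]))
      ok <- dd > 0 & dd <= max_distance_km
      i <- c(i, a[ok]); j <- c(j, b[ok]); d <- c(d, dd[ok])
      tries <- tries + 1L
    }
    n_use <- min(length(i), n_pairs)
    list(i = i[seq_len(n_use)], j = j[seq_len(n_use)], d = d[seq_len(n_use)])
  })
  if (!length(pairs$i)) {
    stop("no cell pairs within max_distance_km; increase the distance cap",
         call. = FALSE)
  }

  edges <- seq(0, max_distance_km, by = class_width_km)
  if (edges[length(edges)] < max_distance_km) edges <- c(edges, max_distance_km)
  cls <- findInterval(pairs$d, edges, rightmost.closed = TRUE)

  rows <- purrr::map_dfr(seq_len(length(edges) - 1L), function(k) {
    sel <- which(cls == k)
    n_k <- length(sel)
    if (n_k < 2L || !any(keep_pred)) {
      return(tibble::tibble(lower_km = edges[k], upper_km = edges[k + 1L],
                            r = NA_real_, n_pairs = n_k, p_value = NA_real_,
                            significant = FALSE))
    }
    x <- as.vector(feats[pairs$i[sel], , drop = FALSE])
    y <- as.vector(feats[pairs$j[sel], , drop = FALSE])
    r <- suppressWarnings(stats::cor(x, y))
    if (is.na(r)) {
      p <- NA_real_
    } else {
      # test at the site-pair count, not the pooled (pairs x predictors) count
      tstat <- r * sqrt((n_k - 2) / max(1 - r^2, 1e-12))
      p <- 2 * stats::pt(-abs(tstat), df = n_k - 2)
    }
    tibble::tibble(lower_km = edges[k], upper_km = edges[k + 1L], r = r,
                   n_pairs = n_k, p_value = p,
                   significant = isTRUE(n_k >= 30L && !is.na(p) &&
                                          p < alpha && r > 0))
  })
  if (all(rows$n_pairs < 30L)) {
    stop("fewer than 30 pairs in every distance class; increase n_pairs",
         call. = FALSE)
  }
  first_ns <- match(FALSE, rows$significant)
  dist_km <- if (is.na(first_ns)) max_distance_km else rows$lower_km[first_ns]
  structure(rows, class = c("correlogram", class(rows)),
            uncorrelated_distance_km = dist_km)
}

#' Uncorrelated distance recorded on a correlogram
#'
#' @param correlogram result of [estimate_autocorrelation_distance()].
#' @return distance in km.
#' @export
uncorrelated_distance <- function(correlogram) {
  attr(correlogram, "uncorrelated_distance_km")
}

#' Thin occurrence records to a minimum pairwise distance
#'
#' Visits records in seeded random order and keeps a record iff no
#' already-kept record lies within `min_distance_km` (great circle). With
#' `min_distance_km = 0` the input is returned unchanged.
#'
#' @param occ data frame with `lon`, `lat`.
#' @param min_distance_km minimum allowed pairwise distance, km.
#' @param seed integer seed for the visiting order.
#' @return tibble of retained records.
#' @export
thin_occurrences <- function(occ, min_distance_km, seed = 1) {
  pts <- normalize_lonlat(occ)
  if (min_distance_km < 0) stop("min_distance_km must be >= 0", call. = FALSE)
  if (min_distance_km == 0 || nrow(pts) <= 1L) return(pts)
  ord <- withr::with_seed(seed, sample.int(nrow(pts)))
  kept <- integer(0)
  kept_mat <- matrix(numeric(0), ncol = 2L)
  for (idx in ord) {
    p <- c(pts$lon[idx], pts$lat[idx])
    if (!nrow(kept_mat) ||
        all(great_circle_km(kept_mat, matrix(p, ncol = 2L)) >= min_distance_km)) {
      kept <- c(kept, idx)
      kept_mat <- rbind(kept_mat, p)
    }
  }
  pts[sort(kept), ]
}
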