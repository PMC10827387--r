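# Climatically structured pseudo-absences: candidate cells are unmasked
# cells outside an exclusion buffer around every occurrence; K-means with
# k = the desired number of pseudo-absences partitions the candidates'
# standardized predictor values, and the candidate nearest each centroid
# becomes one pseudo-absence. Balancing follows the occurrence count:
# one run at a 1:1 ratio for species with more than 1,000 (thinned)
# occurrences, otherwise 10 runs of max(100, n_occ) pseudo-absences each.

#' Generate climatically structured pseudo-absence training sets
#'
#' @param stack a [predictor_stack()] (baseline scenario).
#' @param occ_thinned thinned occurrence tibble (`lon`, `lat`).
#' @param exclusion_km pseudo-absence candidates must lie farther than this
#'   from every occurrence (normally the uncorrelated distance).
#' @param seed integer seed; runs use sub-seeds `seed + run`.
#' @param balance_cutoff occurrence count above which a single 1:1 run is
#'   used (default 1000).
#' @param n_runs_rare number of runs for species at or below the cutoff.
#' @param min_pa minimum pseudo-absences per run for rare species.
#' @param max_candidates cap on the candidate pool fed to K-means; larger
#'   pools are seeded-subsampled for tractability.
#' @return list of training tibbles, one per run, each with columns
#'   `run`, `lon`, `lat`, `label` (1 presence / 0 pseudo-absence) and one
#'   column per predictor. Presences falling on masked cells are dropped.
#' @export
generate_pseudoabsences <- function(stack, occ_thinned, exclusion_km,
                                    seed = 1, balance_cutoff = 1000,
                                    n_runs_rare = 10, min_pa = 100,
                                    max_candidates = 20000) {
  stopifnot(inherits(stack, "predictor_stack"))
  occ <- normalize_lonlat(occ_thinned)
  if (!nrow(occ)) stop("no occurrences supplied", call. = FALSE)

  pres <- extract_values(stack, occ)
  pres <- dplyr::filter(pres, .data$keep)
  if (!nrow(pres)) stop("all occurrences fall on masked cells", call. = FALSE)
  n_occ <- nrow(pres)

  if (n_occ > balance_cutoff) {
    n_pa <- n_occ; n_runs <- 1L
  } else {
    n_pa <- max(min_pa, n_occ); n_runs <- n_runs_rare
  }

  ref <- stack_ref_grid(stack)
  cells <- unmasked_cells(ref)
  cc <- cell_centers(ref, cells)
  # distance to nearest occurrence, chunked to bound memory
  min_d <- rep(Inf, length(cells))
  occ_mat <- as.matrix(occ)
  chunk <- 5000L
  for (start in seq(1L, length(cells), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(cells))
    d <- great_circle_matrix_km(cbind(cc$lon[idx], cc$lat[idx]), occ_mat)
    min_d[idx] <- apply(d, 1L, min)
  }
  cand <- which(min_d > exclusion_km)
  if (length(cand) < n_pa) {
    stop("candidate pool (", length(cand), " cells) smaller than the ",
         n_pa, " pseudo-absences required", call. = FALSE)
  }

  feat_names <- stack_names(stack)
  feats_all <- vapply(stack$grids, function(g) g$values[cells],
                      numeric(length(cells)))

  pres_out <- dplyr::select(pres, "lon", "lat", dplyr::all_of(feat_names))
  pres_out$label <- 1L

  runs <- lapply(seq_len(n_runs), function(run) {
    run_seed <- seed + run
    withr::with_seed(run_seed, {
      cap <- max(max_candidates, n_pa)
      pool <- if (length(cand) > cap) sample(cand, cap) else cand
      X <- feats_all[pool, , drop = FALSE]
      Xs <- scale(X)
      Xs[, attr(Xs, "scaled:scale") == 0] <- 0
      nstart <- if (n_pa <= 250) 10L else 2L
      km <- suppressWarnings(
        stats::kmeans(Xs, centers = n_pa, iter.max = 25L, nstart = nstart,
                      algorithm = "Lloyd"))
      # representative of each cluster: member nearest its centroid; the
      # rare empty Lloyd cluster falls back to the nearest unused candidate
      rep_idx <- integer(n_pa)
      used <- logical(nrow(Xs))
      for (k in seq_len(n_pa)) {
        members <- which(km$cluster == k & !used)
        if (!length(members)) members <- which(!used)
        d2 <- rowSums((Xs[members, , drop = FALSE] -
                         matrix(km$centers[k, ], length(members),
                                ncol(Xs), byrow = TRUE))^2)
        rep_idx[k] <- if (any(is.finite(d2))) members[which.min(d2)]
                      else members[1L]   # empty cluster: NaN centroid
        used[rep_idx[k]] <- TRUE
      }
      pa_rows <- pool[rep_idx]        # row indices into the unmasked-cell table
      pa <- tibble::tibble(lon = cc$lon[pa_rows], lat = cc$lat[pa_rows])
      pa <- dplyr::bind_cols(pa, tibble::as_tibble(
        feats_all[pa_rows, , drop = FALSE]))
      pa$label <- 0L
      pa$cluster <- seq_len(n_pa)
      out <- dplyr::bind_rows(
        dplyr::mutate(pres_out, cluster = NA_integer_), pa)
      out$run <- run
      dplyr::select(out, "run", "lon", "lat", "label", "cluster",
                    dplyr::all_of(feat_names))
    })
  })
  runs
}
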