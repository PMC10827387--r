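# Correlogram estimation, occurrence thinning, hexagon-block folds and
# climatically structured pseudo-absence generation.

test_that("a white-noise world is uncorrelated at the first distance class", {
  w <- make_world(n_rows = 80, n_cols = 80, autocorr_length_km = 0,
                  land_fraction = 0, seed = 12)
  cg <- estimate_autocorrelation_distance(world_stack(w), n_pairs = 4000,
                                          class_width_km = 50,
                                          max_distance_km = 300, seed = 1)
  expect_s3_class(cg, "correlogram")
  expect_false(cg$significant[1])
  expect_equal(uncorrelated_distance(cg), cg$lower_km[1])
  expect_equal(uncorrelated_distance(cg), 0)
})

test_that("a long correlation length yields a plausible distance estimate", {
  # flat predictors (no latitudinal trend) so only the random field's
  # correlation length drives the correlogram
  specs <- list(predictor_spec("salinity", 35, 1),
                predictor_spec("nitrate", 5, 1.5))
  dists <- vapply(1:3, function(s) {
    w <- make_world(n_rows = 120, n_cols = 120, predictor_specs = specs,
                    autocorr_length_km = 300, land_fraction = 0, seed = s,
                    scenario_offsets = list())
    cg <- estimate_autocorrelation_distance(world_stack(w), n_pairs = 5000,
                                            class_width_km = 50,
                                            max_distance_km = 600,
                                            seed = s)
    uncorrelated_distance(cg)
  }, numeric(1))
  expect_true(all(dists >= 150 & dists <= 600))
})

test_that("constant predictors are treated as uncorrelated, not an error", {
  w <- make_world(n_rows = 60, n_cols = 60, land_fraction = 0, seed = 2,
                  predictor_specs = list(predictor_spec("salinity", 35, 1)),
                  scenario_offsets = list())
  w$predictors$salinity[] <- 35   # zero variance everywhere
  expect_warning(
    cg <- estimate_autocorrelation_distance(world_stack(w), n_pairs = 2000,
                                            max_distance_km = 300, seed = 1),
    "zero variance")
  expect_equal(uncorrelated_distance(cg), 0)
})

test_that("thinning collapses a tight cluster to one record", {
  withr::with_seed(4, {
    occ <- tibble::tibble(lon = runif(50, 0, 0.005), lat = runif(50, 0, 0.005))
  })
  th <- thin_occurrences(occ, 10, seed = 1)
  expect_equal(nrow(th), 1)
})

test_that("thinning keeps a regular grid spaced beyond the minimum", {
  grid <- expand.grid(lon = seq(0, 4) * 0.9, lat = seq(0, 4) * 0.9)  # ~100 km
  th <- thin_occurrences(tibble::as_tibble(grid), 50, seed = 2)
  expect_equal(nrow(th), 25)
})

test_that("thinning with zero distance is the identity", {
  occ <- tibble::tibble(lon = c(0, 0.001), lat = c(0, 0.001))
  expect_equal(thin_occurrences(occ, 0, seed = 1), occ)
})

test_that("thinning is idempotent and enforces the pairwise minimum", {
  w <- tiny_world()
  occ <- sample_occurrences(tiny_species(w), 300, seed = 5)
  th <- thin_occurrences(occ, 40, seed = 7)
  d <- great_circle_matrix_km(th, th)
  expect_true(all(d[upper.tri(d)] >= 40))
  expect_equal(thin_occurrences(th, 40, seed = 99), th)
})

test_that("hex folds: mates share folds, every fold occupied", {
  withr::with_seed(21, {
    pts <- tibble::tibble(lon = runif(2000, 0, 12), lat = runif(2000, -6, 6))
  })
  fa <- assign_hex_folds(pts, hex_width_km = 150, n_folds = 10, seed = 3)
  expect_setequal(unique(fa$fold), 1:10)
  # spatial independence contract: one fold per hexagon
  per_hex <- tapply(fa$fold, fa$hex_id, function(f) length(unique(f)))
  expect_true(all(per_hex == 1))
})

test_that("nearby points share a hexagon; too few hexagons is an error", {
  pts <- tibble::tibble(lon = c(0, 0.009), lat = c(0, 0))  # ~1 km apart
  fa <- assign_hex_folds(dplyr::bind_rows(pts, tibble::tibble(
    lon = seq(2, 20, by = 2), lat = rep(0, 10))), 100, n_folds = 2, seed = 1)
  expect_equal(fa$hex_id[1], fa$hex_id[2])
  expect_equal(fa$fold[1], fa$fold[2])
  expect_error(assign_hex_folds(pts, 100, n_folds = 10, seed = 1),
               "hexagon")
})

test_that("fold assignment depends only on (hexagon, seed)", {
  withr::with_seed(33, {
    pts <- tibble::tibble(lon = runif(300, 0, 8), lat = runif(300, -4, 4))
  })
  f1 <- assign_hex_folds(pts, 120, n_folds = 5, seed = 9)
  f2 <- assign_hex_folds(pts[sample.int(300), ], 120, n_folds = 5, seed = 9)
  m <- match(paste(f1$lon, f1$lat), paste(f2$lon, f2$lat))
  expect_identical(f1$fold, f2$fold[m])
})

test_that("pseudo-absence balancing follows the 1:1 / 10-run rule", {
  w <- tiny_world()
  st <- world_stack(w)
  # rare species: 60 occurrences -> 10 runs x 100 pseudo-absences
  occ60 <- sample_occurrences(tiny_species(w), 60, seed = 14)
  occ60 <- dplyr::distinct(occ60)
  runs <- generate_pseudoabsences(st, occ60, exclusion_km = 30, seed = 2)
  expect_length(runs, 10)
  for (r in runs) expect_equal(sum(r$label == 0), 100)
  expect_equal(sum(runs[[1]]$label == 1), nrow(occ60))
})

test_that("pseudo-absences stay outside the exclusion buffer", {
  w <- tiny_world()
  st <- world_stack(w)
  occ <- dplyr::distinct(sample_occurrences(tiny_species(w), 40, seed = 3))
  runs <- generate_pseudoabsences(st, occ, exclusion_km = 50, seed = 4)
  pa <- runs[[1]][runs[[1]]$label == 0, ]
  d <- great_circle_matrix_km(pa, occ)
  expect_true(all(d > 50))
})

test_that("each pseudo-absence represents a distinct K-means cluster", {
  w <- tiny_world()
  st <- world_stack(w)
  occ <- dplyr::distinct(sample_occurrences(tiny_species(w), 30, seed = 6))
  runs <- generate_pseudoabsences(st, occ, exclusion_km = 30, seed = 5)
  pa <- runs[[1]][runs[[1]]$label == 0, ]
  expect_equal(length(unique(pa$cluster)), nrow(pa))
  # and distinct locations
  expect_equal(nrow(dplyr::distinct(pa[, c("lon", "lat")])), nrow(pa))
})

test_that("structured pseudo-absences cover predictor space at least as
           well as random sampling", {
  w <- tiny_world()
  st <- world_stack(w)
  occ <- dplyr::distinct(sample_occurrences(tiny_species(w), 30, seed = 8))
  ref <- oceanrange:::stack_ref_grid(st)
  cells <- unmasked_cells(ref)
  feats <- vapply(st$grids, function(g) g$values[cells], numeric(length(cells)))
  feats <- scale(feats)
  coverage <- function(pa_feats) {
    d <- as.matrix(stats::dist(rbind(pa_feats, feats)))
    n <- nrow(pa_feats)
    max(apply(d[(n + 1):nrow(d), 1:n, drop = FALSE], 1, min))
  }
  km_cov <- ran_cov <- numeric(5)
  for (s in 1:5) {
    runs <- generate_pseudoabsences(st, occ, exclusion_km = 30, seed = s,
                                    n_runs_rare = 1)
    pa <- runs[[1]][runs[[1]]$label == 0, ]
    km_cov[s] <- coverage(scale(as.matrix(pa[, colnames(feats)]),
                                center = attr(feats, "scaled:center"),
                                scale = attr(feats, "scaled:scale")))
    ran_cells <- withr::with_seed(s, sample(cells, nrow(pa)))
    ran_cov[s] <- coverage(feats[match(ran_cells, cells), , drop = FALSE])
  }
  expect_lte(mean(km_cov), mean(ran_cov))
})

test_that("a too-small candidate pool is an error", {
  w <- tiny_world()
  st <- world_stack(w)
  occ <- dplyr::distinct(sample_occurrences(tiny_species(w), 40, seed = 9))
  expect_error(generate_pseudoabsences(st, occ, exclusion_km = 5000, seed = 1),
               "candidate pool")
})
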