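# Ensemble weighting, suitability/uncertainty maps, reclassification,
# depth restriction and stepping-stone dispersal clipping.

make_const_model <- function(value, features = c("temp_max", "salinity")) {
  # a degenerate sdm_model stand-in with a constant response, for pure
  # ensemble arithmetic tests
  structure(list(algorithm = "brt", features = features,
                 hyperparams = tibble::tibble(), monotone = NULL,
                 const = value, n_presence = 1, n_absence = 1),
            class = c("const_model", "sdm_model"))
}

predict.const_model <- function(object, newdata, ...) {
  rep(object$const, nrow(as.data.frame(newdata)))
}
registerS3method("predict", "const_model", predict.const_model,
                 envir = asNamespace("stats"))

test_that("equal metrics give equal weights; single model gets weight 1", {
  ms <- list(a = make_const_model(0.2), b = make_const_model(0.5),
             c = make_const_model(0.8))
  ms$a$algorithm <- "brt"; ms$b$algorithm <- "adaboost"; ms$c$algorithm <- "xgb"
  ens <- build_ensemble(unname(ms), c(brt = 0.8, adaboost = 0.8, xgb = 0.8))
  expect_equal(unname(ens$weights), rep(1 / 3, 3))
  single <- build_ensemble(list(ms$a), c(brt = 0.9))
  expect_equal(unname(single$weights), 1)
  probe <- tibble::tibble(temp_max = 1:3, salinity = 4:6)
  expect_equal(predict(single, probe), predict(ms$a, probe))
})

test_that("AUC weights subtract the 0.5 random-skill floor", {
  ms <- list(make_const_model(0.2), make_const_model(0.5),
             make_const_model(0.8))
  ms[[1]]$algorithm <- "brt"; ms[[2]]$algorithm <- "adaboost"
  ms[[3]]$algorithm <- "xgb"
  ens <- build_ensemble(ms, c(brt = 0.9, adaboost = 0.7, xgb = 0.5))
  expect_equal(unname(ens$weights[c("brt", "adaboost", "xgb")]),
               c(2 / 3, 1 / 3, 0))
  expect_equal(sum(ens$weights), 1)
})

test_that("all-floor metrics fall back to equal weights with a warning", {
  ms <- list(make_const_model(0.2), make_const_model(0.8))
  ms[[2]]$algorithm <- "xgb"
  expect_warning(ens <- build_ensemble(ms, c(brt = 0.5, xgb = 0.4)),
                 "equal weights")
  expect_equal(unname(ens$weights), c(0.5, 0.5))
  expect_error(build_ensemble(list(), c(brt = 1)), "empty")
})

const_stack <- function(n = 6) {
  v <- matrix(1, n, n); v[1, 1] <- NA
  predictor_stack(list(
    temp_max = raster_grid(v * 15, 0, n * 0.05, 0.05),
    salinity = raster_grid(v * 35, 0, n * 0.05, 0.05)), "baseline")
}

test_that("identical members give zero uncertainty; 0/1 members give the
           closed-form sd", {
  st <- const_stack()
  same <- list(make_const_model(0.7), make_const_model(0.7))
  same[[2]]$algorithm <- "xgb"
  ens <- build_ensemble(same, c(brt = 0.9, xgb = 0.9))
  pred <- ensemble_predict(ens, st)
  expect_true(all(pred$uncertainty$values[-1] == 0))
  expect_true(all(pred$suitability$values[-1] == 0.7))

  duo <- list(make_const_model(0), make_const_model(1))
  duo[[2]]$algorithm <- "xgb"
  ens2 <- build_ensemble(duo, c(brt = 0.9, xgb = 0.9))
  pred2 <- ensemble_predict(ens2, st)
  expect_equal(pred2$suitability$values[2, 2], 0.5)
  expect_equal(pred2$uncertainty$values[2, 2], sd(c(0, 1)))  # 1/sqrt(2)
  expect_true(is.na(pred2$suitability$values[1, 1]))
  expect_true(is.na(pred2$uncertainty$values[1, 1]))
})

test_that("the ensemble map is a convex combination of member maps", {
  w <- tiny_world()
  st <- world_stack(w)
  occ <- dplyr::distinct(sample_occurrences(tiny_species(w), 50, seed = 4))
  runs <- generate_pseudoabsences(st, occ, exclusion_km = 30, seed = 2,
                                  n_runs_rare = 1)
  tr <- runs[[1]]
  m1 <- fit_model(tr, "brt", list(learning_rate = 0.1, tree_complexity = 2,
                                  n_trees = 50), seed = 1)
  m2 <- fit_model(tr, "xgb", list(gamma = 0, interaction_depth = 2,
                                  shrinkage = 0.3, n_rounds = 30), seed = 1)
  ens <- build_ensemble(list(m1, m2), c(brt = 0.8, xgb = 0.95))
  pred <- ensemble_predict(ens, st)
  v1 <- predict_map(m1, st)$values; v2 <- predict_map(m2, st)$values
  lo <- pmin(v1, v2); hi <- pmax(v1, v2)
  ok <- !is.na(lo)
  expect_true(all(pred$suitability$values[ok] >= lo[ok] - 1e-12))
  expect_true(all(pred$suitability$values[ok] <= hi[ok] + 1e-12))
  expect_true(all(pred$uncertainty$values[ok] >= 0))
})

test_that("reclassification thresholds with ties predicted present", {
  suit <- raster_grid(matrix(c(0.2, 0.5, 0.8, NA), 2, 2), 0, 1, 0.5)
  rm0 <- reclassify(suit, 0)
  expect_true(all(rm0$values[!is.na(rm0$values)] == 1))
  rm1 <- reclassify(suit, 1)
  expect_true(all(rm1$values[!is.na(rm1$values)] == 0))
  rm <- reclassify(suit, 0.5)
  expect_equal(as.vector(rm$values), c(0, 1, 1, NA))
  expect_true(is.na(rm$values[2, 2]))
})

test_that("depth clipping removes deep presences only, idempotently", {
  v <- matrix(1, 3, 3)
  g <- raster_grid(v, 0, 1, 0.05)
  rm <- oceanrange:::range_map_grid(v, g, "baseline", 0.5, "mtp")
  bathy <- raster_grid(matrix(c(10, 20, 40, 100, 400, 500, 600, 31, 29),
                              3, 3), 0, 1, 0.05)
  clipped <- clip_depth(rm, bathy, 30)
  expect_equal(sum(clipped$values == 1), 3)   # depths 10, 20, 29 survive
  expect_true(all(clipped$values[bathy$values > 30] == 0))
  expect_identical(clip_depth(clipped, bathy, 30)$values, clipped$values)
  # max depth beyond the deepest cell leaves the map unchanged
  expect_identical(clip_depth(rm, bathy, 1000)$values, rm$values)
  bad <- raster_grid(matrix(1, 2, 2), 0, 1, 0.05)
  expect_error(clip_depth(rm, bad, 30), "co-registered")
})

test_that("dispersal clipping removes patches beyond the step limit", {
  # two patches; gap 250 km -> patch B removed; gap 150 km -> retained
  occA <- tibble::tibble(lon = 0.125, lat = 0)
  wide <- two_patch_map(gap_cells = 45)    # 45 * 5.566 ~ 250 km
  out <- clip_dispersal(wide, occA, max_step_km = 200)
  expect_equal(sum(out$values[, 1:8]), sum(wide$values[, 1:8]))
  expect_equal(sum(out$values[, 54:61]), 0)
  narrow <- two_patch_map(gap_cells = 27)  # ~150 km
  out2 <- clip_dispersal(narrow, occA, max_step_km = 200)
  expect_equal(out2$values, narrow$values)
})

test_that("occurrence records rescue an otherwise unreachable patch", {
  wide <- two_patch_map(gap_cells = 45)
  occ_b <- tibble::tibble(lon = c(0.125, 57 * 0.05 + 0.025), lat = c(0, 0))
  out <- clip_dispersal(wide, occ_b, max_step_km = 200)
  expect_equal(out$values, wide$values)
})

test_that("dispersal clipping equals the BFS reachability oracle", {
  skip_if_not_installed("igraph")
  withr::with_seed(47, {
    for (k in 1:4) {
      v <- matrix(rbinom(50 * 50, 1, 0.25), 50, 50)
      g <- raster_grid(v, 0, 50 * 0.05 / 2, 0.05)
      rm <- oceanrange:::range_map_grid(v, g, "baseline", 0.5, "mtp")
      pres <- which(v == 1)
      occ_cells <- sample(pres, 3)
      occ <- cell_centers(g, occ_cells)[, c("lon", "lat")]
      ours <- clip_dispersal(rm, occ, max_step_km = 20)
      oracle <- oracle_dispersal(rm, occ, max_step_km = 20)
      expect_identical(ours$values, oracle)
    }
  })
})

test_that("dispersal clipping is idempotent and warns without seeds", {
  wide <- two_patch_map(gap_cells = 45)
  occA <- tibble::tibble(lon = 0.125, lat = 0)
  once <- clip_dispersal(wide, occA, max_step_km = 200)
  twice <- clip_dispersal(once, occA, max_step_km = 200)
  expect_identical(once$values, twice$values)
  expect_warning(out <- clip_dispersal(wide, tibble::tibble(lon = numeric(0),
                                                            lat = numeric(0))),
                 "no occurrences")
  expect_identical(out$values, wide$values)
})

test_that("project_scenarios: identity futures, threshold transfer, file
           contract", {
  w <- tiny_world()
  st <- world_stack(w)
  sp <- tiny_species(w)
  occ <- dplyr::distinct(sample_occurrences(sp, 60, seed = 11))
  runs <- generate_pseudoabsences(st, occ, exclusion_km = 30, seed = 3,
                                  n_runs_rare = 1)
  tr <- runs[[1]]
  m <- fit_model(tr, "xgb", list(gamma = 0, interaction_depth = 2,
                                 shrinkage = 0.3, n_rounds = 30), seed = 2)
  ens <- build_ensemble(list(m), c(xgb = 0.9), max_depth_m = 600)
  pres_scores <- predict(ens, tr[tr$label == 1, ])
  ens$threshold <- mtp_threshold(pres_scores)$threshold

  stacks <- list(baseline = st, ssp585 = st)  # future identical to baseline
  maps <- project_scenarios(ens, stacks, occ, world_bathymetry(w))
  expect_named(maps, c("baseline", "ssp585"))
  for (sc in names(maps)) {
    expect_named(maps[[sc]], c("suitability", "uncertainty", "range"))
    expect_equal(attr(maps[[sc]]$range, "threshold"), ens$threshold)
  }
  expect_identical(maps$baseline$suitability$values,
                   maps$ssp585$suitability$values)
  expect_identical(maps$baseline$range$values, maps$ssp585$range$values)
  # training sensitivity of the thresholded (unclipped) baseline map
  base_bin <- reclassify(maps$baseline$suitability, ens$threshold)
  loc <- locate_cells(base_bin, occ$lon, occ$lat)
  expect_gte(mean(base_bin$values[loc$cell] == 1, na.rm = TRUE), 0.95)
  # clips only remove presences
  expect_true(all(maps$baseline$range$values <= base_bin$values, na.rm = TRUE))
})

test_that("warming beyond the thermal limit contracts the future range", {
  w <- tiny_world()
  sp <- tiny_species(w)
  occ <- dplyr::distinct(sample_occurrences(sp, 60, seed = 13))
  st <- world_stack(w)
  runs <- generate_pseudoabsences(st, occ, exclusion_km = 30, seed = 5,
                                  n_runs_rare = 1)
  tr <- add_hex_folds(runs[[1]], 100, n_folds = 4, seed = 1)
  m <- fit_model(tr, "brt", list(learning_rate = 0.1, tree_complexity = 2,
                                 n_trees = 100), seed = 3)
  ens <- build_ensemble(list(m), c(brt = 0.95))
  ens$threshold <- mtp_threshold(predict(ens, tr[tr$label == 1, ]))$threshold
  stacks <- list(baseline = st, ssp585 = world_stack(w, "ssp585"))
  maps <- project_scenarios(ens, stacks, occ)
  a_base <- range_area(maps$baseline$range)$n_presence
  a_fut <- range_area(maps$ssp585$range)$n_presence
  expect_lt(a_fut, a_base)
})

test_that("a future scenario missing a dynamic layer errors", {
  w <- tiny_world()
  st <- world_stack(w)
  m <- make_const_model(0.7, features = names(st$grids))
  ens <- build_ensemble(list(m), c(brt = 0.9))
  ens$threshold <- 0.5
  broken <- predictor_stack(st$grids[-1], "ssp119")
  expect_error(project_scenarios(ens, list(baseline = st, ssp119 = broken),
                                 tibble::tibble(lon = 1, lat = 0)),
               "missing layer")
})
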