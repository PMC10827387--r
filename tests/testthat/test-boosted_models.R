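# Grid enumeration, monotone-constrained fitting, cross-validation and
# map prediction.

test_that("reference hyperparameter lattices enumerate to the right sizes", {
  brt <- enumerate_grid("brt")
  ada <- enumerate_grid("adaboost")
  xgb <- enumerate_grid("xgb")
  expect_equal(nrow(brt), 240)   # 3 x 4 x 20
  expect_equal(nrow(ada), 240)   # 5 x 12 x 4
  expect_equal(nrow(xgb), 1200)  # 6 x 4 x 5 x 10
  # axes exactly as specified
  expect_setequal(unique(brt$learning_rate), c(0.1, 0.01, 0.001))
  expect_setequal(unique(brt$tree_complexity), 1:4)
  expect_setequal(unique(brt$n_trees), seq(50, 1000, 50))
  expect_setequal(unique(ada$n_iterations), seq(50, 250, 50))
  expect_setequal(unique(ada$degrees_freedom), 1:12)
  expect_setequal(unique(ada$shrinkage), seq(0.25, 1, 0.25))
  expect_setequal(unique(xgb$gamma), 0:5)
  expect_setequal(unique(xgb$interaction_depth), 1:4)
  expect_setequal(unique(xgb$shrinkage), seq(0.1, 0.5, 0.1))
  expect_setequal(unique(xgb$n_rounds), seq(10, 100, 10))
  expect_error(enumerate_grid("maxent"), "unknown algorithm")
})

fit_each <- function(train, seed = 1, mono = c(temp_max = -1L, salinity = 1L)) {
  list(
    brt = fit_model(train, "brt",
                    list(learning_rate = 0.1, tree_complexity = 2,
                         n_trees = 100), mono, seed = seed),
    adaboost = fit_model(train, "adaboost",
                         list(n_iterations = 100, degrees_freedom = 4,
                              shrinkage = 0.5), mono, seed = seed),
    xgb = fit_model(train, "xgb",
                    list(gamma = 0, interaction_depth = 2, shrinkage = 0.3,
                         n_rounds = 50), mono, seed = seed))
}

test_that("all three algorithms separate a separable toy set perfectly", {
  train <- toy_training()
  for (m in fit_each(train)) {
    p <- predict(m, train)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sdm_auc(train$label, p), 1)
  }
})

test_that("partial dependence respects the monotone constraints exactly", {
  train <- toy_training(fuzz = 0.1)  # noisy so trees are non-trivial
  for (m in fit_each(train)) {
    pd_t <- partial_dependence(m, train, "temp_max", n_grid = 40)
    expect_true(all(diff(pd_t$suitability) <= 1e-9),
                label = paste(m$algorithm, "non-increasing in temp_max"))
    pd_s <- partial_dependence(m, train, "salinity", n_grid = 40)
    expect_true(all(diff(pd_s$suitability) >= -1e-9),
                label = paste(m$algorithm, "non-decreasing in salinity"))
  }
})

test_that("fits are deterministic given (train, hyperparams, seed)", {
  train <- toy_training(fuzz = 0.15)
  probe <- toy_training(n = 60, seed = 2)
  for (a in c("brt", "adaboost", "xgb")) {
    hp <- hyper_grid(a, "reduced")[3, ]
    m1 <- fit_model(train, a, hp, c(temp_max = -1L, salinity = 1L), seed = 5)
    m2 <- fit_model(train, a, hp, c(temp_max = -1L, salinity = 1L), seed = 5)
    expect_identical(predict(m1, probe), predict(m2, probe))
  }
})

test_that("fitting guards: classes, monotone coverage, lattice warning", {
  train <- toy_training()
  hp <- list(learning_rate = 0.1, tree_complexity = 2, n_trees = 100)
  expect_error(fit_model(dplyr::filter(train, label == 1), "brt", hp),
               "both classes")
  expect_error(fit_model(train, "brt", hp, monotone_map = c(temp_max = -1L)),
               "salinity")
  expect_warning(fit_model(train, "brt",
                           list(learning_rate = 0.05, tree_complexity = 2,
                                n_trees = 100),
                           c(temp_max = -1L, salinity = 1L)),
                 "lattice")
})

test_that("cross-validation returns the single grid point and full report", {
  train <- toy_training(n = 200, fuzz = 0.1)
  grid <- tibble::tibble(learning_rate = 0.1, tree_complexity = 2, n_trees = 50)
  cv <- cross_validate(train, "brt", grid,
                       monotone_map = c(temp_max = -1L, salinity = 1L),
                       seed = 1)
  expect_equal(nrow(cv$folds), 4)   # one row per fold
  expect_equal(cv$best$learning_rate, 0.1)
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1, na.rm = TRUE))
})

test_that("cross-validation selection is reproducible and prefers skill", {
  train <- toy_training(n = 240, fuzz = 0.2, seed = 4)
  grid <- hyper_grid("xgb", "reduced")[c(1, 4, 9, 16), ]
  mono <- c(temp_max = -1L, salinity = 1L)
  cv1 <- cross_validate(train, "xgb", grid, mono, seed = 8)
  cv2 <- cross_validate(train, "xgb", grid, mono, seed = 8)
  expect_identical(cv1$best, cv2$best)
  expect_equal(max(cv1$summary$auc), cv1$best$auc)
})

test_that("a fold without presences is rejected with a clear signal", {
  train <- toy_training(n = 80)
  train$fold <- ifelse(train$label == 1, 1L, 2L)
  train$fold[train$label == 1][1:5] <- 3L
  grid <- tibble::tibble(learning_rate = 0.1, tree_complexity = 1, n_trees = 50)
  expect_error(cross_validate(train, "brt", grid,
                              c(temp_max = -1L, salinity = 1L)),
               "without presences")
})

test_that("predict_map matches pointwise predictions and keeps the mask", {
  w <- tiny_world()
  st <- world_stack(w)
  sp <- tiny_species(w)
  occ <- dplyr::distinct(sample_occurrences(sp, 40, seed = 2))
  runs <- generate_pseudoabsences(st, occ, exclusion_km = 30, seed = 3)
  m <- fit_model(runs[[1]], "xgb",
                 list(gamma = 0, interaction_depth = 2, shrinkage = 0.3,
                      n_rounds = 30), default_monotone_map(), seed = 1)
  sm <- predict_map(m, st)
  expect_identical(is.na(sm$values), w$land)
  v <- sm$values[!is.na(sm$values)]
  expect_true(all(v >= 0 & v <= 1))
  ref <- oceanrange:::stack_ref_grid(st)
  withr::with_seed(9, cells <- sample(unmasked_cells(ref), 100))
  pts <- cell_centers(ref, cells)
  ex <- extract_values(st, pts)
  expect_equal(sm$values[cells], predict(m, ex))
})

test_that("predict_map requires every model feature in the stack", {
  w <- tiny_world()
  st <- world_stack(w)
  train <- toy_training()
  m <- fit_model(train, "brt",
                 list(learning_rate = 0.1, tree_complexity = 1, n_trees = 50),
                 c(temp_max = -1L, salinity = 1L), seed = 1)
  st_small <- predictor_stack(st$grids["temp_max"], "baseline")
  expect_error(predict_map(m, st_small), "salinity")
})
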