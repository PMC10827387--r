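# Shared fixtures and independent oracles. Worlds are cached per session so
# expensive stages are built once and reused across test files.

world_cache <- new.env(parent = emptyenv())

# small coastal world: fast default for unit tests
tiny_world <- function(seed = 3, ...) {
  key <- paste0("tiny", seed, paste(c(...), collapse = "_"))
  if (is.null(world_cache[[key]])) {
    world_cache[[key]] <- make_world(n_rows = 60, n_cols = 60,
                                     autocorr_length_km = 30, seed = seed, ...)
  }
  world_cache[[key]]
}

# sharp-limit virtual species on a tiny world
tiny_species <- function(world = tiny_world()) {
  make_virtual_species(
    world,
    list(temp_max = c(-Inf, -Inf, 18.5, 19.5), nitrate = c(4, 5, Inf, Inf)),
    max_depth_m = 600)
}

# small separable training set: one informative predictor, presences where
# temp_max is low
toy_training <- function(n = 120, seed = 1, fuzz = 0) {
  withr::with_seed(seed, {
    x <- runif(n, 10, 26)
    y <- as.integer(x < 18)
    if (fuzz > 0) {
      flip <- sample.int(n, ceiling(fuzz * n))
      y[flip] <- 1L - y[flip]
    }
    tibble::tibble(lon = runif(n, 0, 5), lat = runif(n, -2, 2),
                   label = y, temp_max = x, salinity = rnorm(n, 35, 1),
                   fold = rep_len(1:4, n))
  })
}

# brute-force AUC oracle: all presence x absence pairs, ties count 1/2
oracle_auc <- function(labels, scores) {
  p <- scores[labels == 1]; a <- scores[labels == 0]
  cmp <- outer(p, a, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# binary two-patch range map at the equator: patches of `patch_cells`
# columns separated by `gap_cells` unsuitable columns, one row strip
two_patch_map <- function(gap_cells, patch_cells = 8, cell = 0.05,
                          n_rows = 5) {
  n_cols <- 2 * patch_cells + gap_cells
  v <- matrix(0, n_rows, n_cols)
  v[, seq_len(patch_cells)] <- 1
  v[, (patch_cells + gap_cells + 1):n_cols] <- 1
  g <- raster_grid(v, west = 0, north = n_rows * cell / 2, cell = cell)
  oceanrange:::range_map_grid(v, g, "baseline", 0.5, "mtp")
}

# BFS reachability oracle over presence cells with <= max_step_km edges,
# seeded from occurrence cells (igraph connected components)
oracle_dispersal <- function(range_map, occurrences, max_step_km) {
  v <- range_map$values
  pres <- which(v == 1)
  loc <- locate_cells(range_map, occurrences$lon, occurrences$lat)
  seeds <- unique(loc$cell[loc$inside])
  nodes <- union(pres, seeds)
  cc <- cell_centers(range_map, nodes)
  d <- great_circle_matrix_km(cbind(cc$lon, cc$lat), cbind(cc$lon, cc$lat))
  adj <- d <= max_step_km
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  reached <- nodes[comp %in% unique(comp[nodes %in% seeds])]
  out <- v
  out[setdiff(pres, reached)] <- 0
  out
}
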