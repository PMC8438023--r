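# shared fixture builders -- everything is generated in code, nothing on disk

# small all-land grid for unit tests
toy_grid <- function(n_rows = 4, n_cols = 5, res = 0.5) {
  study_grid(0, n_cols * res, 0, n_rows * res, resolution = res,
             land_mask = matrix(TRUE, n_rows, n_cols))
}

# climate stack from a named list of matrices (or a single matrix as bio1)
toy_stack <- function(grid, layers, scenario = "present", gcm = "CCSM") {
  if (is.matrix(layers)) layers <- list(bio1 = layers)
  climate_stack(layers, scenario, gcm, grid)
}

# brute-force envelope oracle: no sorting, direct comparison counting
oracle_score <- function(train, probe) {
  n <- nrow(train)
  apply(probe, 1L, function(x) {
    f <- vapply(seq_along(x), function(j) {
      p <- (sum(train[, j] < x[j]) + 0.5 * sum(train[, j] == x[j])) / n
      2 * min(p, 1 - p)
    }, numeric(1))
    min(f)
  })
}

# random occurrence data.frame on a grid
random_points <- function(grid, n, seed) {
  set.seed(seed)
  data.frame(species = "sp",
             lon = runif(n, grid$lon_min, grid$lon_max - 1e-6),
             lat = runif(n, grid$lat_min + 1e-6, grid$lat_max),
             source = "test")
}

# small synthetic scenario used across tests (fast: 40 x 40 cells)
small_scenario <- function(seed = 11, ...) {
  synthetic_scenario(seed = seed, grid = study_grid(100, 120, 0, 20, 0.5),
                     n_pop_clusters = 2, pop_factor = 4, ...)
}
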