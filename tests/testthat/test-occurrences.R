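land_checker_grid <- function() {
  mask <- matrix(TRUE, 4, 5)
  mask[1, 1] <- FALSE  # an ocean cell in the northwest corner
  study_grid(0, 2.5, 0, 2, 0.5, land_mask = mask)
}

test_that("cleaning removes duplicates, off-extent and ocean records with reasons", {
  g <- land_checker_grid()
  recs <- data.frame(
    species = c("a", "a", "a", "a", "b", ""),
    lon = c(1.1, 1.1, 160, 0.2, 1.3, 1.0),
    lat = c(1.1, 1.1, 1.0, 1.9, 0.4, 1.0),   # (0.2, 1.9) is the ocean cell
    source = "t")
  set <- suppressWarnings(clean_occurrences(recs, g))
  expect_equal(nrow(set$records) + nrow(set$dropped), nrow(recs))
  expect_equal(sort(set$dropped$reason),
               sort(c("duplicate", "outside_extent", "not_land", "unparseable")))
  expect_equal(nrow(set$records), 2)
  # first-seen duplicate survives
  expect_true(any(set$records$species == "a" & set$records$lon == 1.1))
})

test_that("small samples trigger a warning but are retained", {
  g <- toy_grid()
  recs <- data.frame(species = "rare", lon = c(0.1, 0.6), lat = c(0.1, 0.6),
                     source = "t")
  expect_warning(set <- clean_occurrences(recs, g, min_n = 20), "below 20")
  expect_equal(nrow(set$records), 2)
})

test_that("grid thinning keeps one first-seen record per species per cell", {
  g <- toy_grid()
  recs <- data.frame(species = "a",
                     lon = c(0.10, 0.12, 0.20, 0.15, 0.22),  # all in cell 1
                     lat = rep(1.9, 5), source = letters[1:5])
  set <- thin_to_grid(suppressWarnings(clean_occurrences(recs, g)), g)
  expect_equal(nrow(set$records), 1)
  expect_equal(set$records$source, "a")
  expect_equal(sum(set$dropped$reason == "thinned"), 4)
  # records in distinct cells are untouched
  apart <- data.frame(species = "a", lon = c(0.1, 0.6, 1.1), lat = 1.9,
                      source = "t")
  set2 <- thin_to_grid(suppressWarnings(clean_occurrences(apart, g)), g)
  expect_equal(nrow(set2$records), 3)
})

test_that("thinning to k engineered cells leaves exactly k records", {
  g <- toy_grid(6, 6)
  k <- 7
  cc <- cell_centers(g)
  cells <- expand.grid(row = 1:6, col = 1:6)[seq_len(k), ]
  base <- data.frame(species = "a", lon = cc$lon[cells$col],
                     lat = cc$lat[cells$row], source = "t")
  noise <- base[rep(1:k, each = 3), ]
  noise$lon <- noise$lon + runif(nrow(noise), 0, 0.2)  # still same cells
  set <- thin_to_grid(suppressWarnings(clean_occurrences(rbind(base, noise), g)), g)
  expect_equal(nrow(set$records), k)
})

test_that("thinning is idempotent and never increases counts", {
  g <- toy_grid(8, 8)
  recs <- random_points(g, 60, seed = 13)
  recs$species <- rep(c("a", "b"), 30)
  set1 <- thin_to_grid(suppressWarnings(clean_occurrences(recs, g)), g)
  set2 <- thin_to_grid(set1, g)
  expect_equal(set1$records, set2$records)
  c_in <- species_counts(recs); c_out <- species_counts(set1)
  expect_true(all(c_out$n <= c_in$n[match(c_out$species, c_in$species)]))
})

test_that("distance thinning enforces the minimum separation", {
  recs <- data.frame(species = "a", lon = c(0, 0.01, 5), lat = c(0, 0, 0),
                     source = "t")
  set <- thin_by_distance(recs, min_km = 100)
  expect_equal(nrow(set$records), 2)
  expect_equal(set$records$lon, c(0, 5))
})

test_that("species counts sum to the retained total", {
  g <- toy_grid(8, 8)
  recs <- random_points(g, 40, seed = 17)
  recs$species <- sample(c("x", "y", "z"), 40, replace = TRUE)
  set <- suppressWarnings(clean_occurrences(recs, g))
  tab <- species_counts(set)
  expect_equal(sum(tab$n), nrow(set$records))
  expect_equal(species_counts(data.frame(species = character(0),
                                         lon = numeric(0), lat = numeric(0))),
               data.frame(species = character(0), n = integer(0)))
})

test_that("occurrence CSV and drop-log round-trip through disk", {
  g <- toy_grid()
  recs <- data.frame(species = c("a", "a"), lon = c(0.1, 99), lat = c(0.1, 0.1),
                     source = "t")
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(recs, p, row.names = FALSE)
  set <- suppressWarnings(clean_occurrences(read_occurrences(p), g))
  lp <- withr::local_tempfile(fileext = ".csv")
  write_drop_log(set, lp)
  log <- utils::read.csv(lp)
  expect_equal(log$reason, "outside_extent")
  expect_error(read_occurrences({
    q <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(x = 1), q, row.names = FALSE); q
  }), "species,lon,lat")
})
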