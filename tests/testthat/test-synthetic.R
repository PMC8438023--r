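test_that("generation is deterministic under a seed and varies across seeds", {
  s1 <- small_scenario(seed = 5)
  s2 <- small_scenario(seed = 5)
  s3 <- small_scenario(seed = 6)
  expect_identical(make_climate(s1), make_climate(s2))
  expect_identical(s1$true_envelope, s2$true_envelope)
  expect_false(identical(make_climate(s1)$present[[1]]$layers,
                         make_climate(s3)$present[[1]]$layers))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(make_climate(s1)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("zero shift and zero perturbation freeze the future climate", {
  scn <- small_scenario(seed = 7, shift_frac = 0, gcm_frac = 0)
  cl <- make_climate(scn)
  for (g in scn$gcms)
    expect_identical(cl$rcp60[[g]]$layers, cl$present[[g]]$layers)
})

test_that("a uniform temperature shift moves bio1 by the stated amount", {
  scn <- small_scenario(seed = 8, vars = c(1, 4), shift_frac = c(0.06, 0.06),
                        gcm_frac = 0)
  cl <- make_climate(scn)
  span <- 35 + 1  # bio1 span in the generator's unit table
  q <- span / 1000
  expected <- q * round(0.06 * span / q)
  delta <- cl$rcp60[[1]]$layers$bio1 - cl$present[[1]]$layers$bio1
  expect_true(all(abs(delta - expected) < 1e-9))
})

test_that("generated precipitation is non-negative and on-lattice", {
  scn <- small_scenario(seed = 9)
  cl <- make_climate(scn)
  for (ep in c("present", "rcp60"))
    for (v in grep("bio1[2-9]", names(cl[[ep]][[1]]$layers), value = TRUE))
      expect_true(all(cl[[ep]][[1]]$layers[[v]] >= 0))
})

test_that("occurrences fall strictly inside the true envelope on land", {
  scn <- small_scenario(seed = 10)
  occ <- make_occurrences(scn, n = 100)
  expect_equal(nrow(occ$records), 100)
  cl <- make_climate(scn)
  vals <- extract_values(cl$present[[1]], occ$records)$values
  for (v in names(scn$true_envelope)) {
    b <- scn$true_envelope[[v]]
    expect_true(all(vals[, v] > b["lo"] & vals[, v] < b["hi"]))
  }
  land <- scn$grid$land_mask
  expect_true(all(land[cbind(occ$records$row, occ$records$col)]))
  truth <- attr(occ, "truth_mask")
  expect_true(all(truth[cbind(occ$records$row, occ$records$col)]))
})

test_that("occurrence samples are nested so envelope coverage grows", {
  scn <- small_scenario(seed = 12)
  small <- make_occurrences(scn, n = 30)
  large <- make_occurrences(scn, n = 300)
  key <- function(s) paste(s$records$row, s$records$col)
  expect_true(all(key(small) %in% key(large)))
  cl <- make_climate(scn)
  fit_mask <- function(occ) {
    m <- env_fit(extract_values(cl$present[[1]], occ$records)$values)
    binarize(predict(m, cl$present[[1]]))
  }
  expect_true(all(fit_mask(large) >= fit_mask(small)))
})

test_that("oversampling and degenerate envelopes are rejected with diagnostics", {
  scn <- small_scenario(seed = 13)
  expect_error(make_occurrences(scn, n = 1e6), "only")
  expect_error(small_scenario(seed = 13,
                              envelope_quantiles = c(0.5, 0.500001)),
               "degenerate")
})

test_that("population rasters are clustered, integral and growth-scaled", {
  scn <- small_scenario(seed = 14)
  p20 <- make_population(scn, "2020", factor = 4)
  expect_equal(dim(p20), dim(scn$grid$land_mask) * 4)
  expect_true(all(p20 >= 0))
  expect_true(all(p20 == round(p20)))
  # growth factor 1 reproduces 2020 exactly
  flat <- small_scenario(seed = 14, pop_growth = 1)
  expect_identical(make_population(flat, "2070", factor = 4),
                   make_population(flat, "2020", factor = 4))
  # uniform doubling doubles every count (and hence every zone density)
  twice <- small_scenario(seed = 14, pop_growth = 2)
  expect_identical(make_population(twice, "2070", factor = 4),
                   2L * make_population(twice, "2020", factor = 4))
})

test_that("a single cluster inside zone 3 leaves other zones unchanged", {
  scn <- synthetic_scenario(seed = 15, grid = study_grid(0, 10, 0, 10, 0.5),
                            n_pop_clusters = 1, pop_factor = 2, pop_peak = 80,
                            pop_growth = 1.5)
  p20 <- aggregate_population(make_population(scn, "2020", factor = 2), 2)
  p70 <- aggregate_population(make_population(scn, "2070", factor = 2), 2)
  hot <- which(p20 == max(p20), arr.ind = TRUE)[1, ]
  # zone 3 around the population peak; zones 1 and 2 in the far corner,
  # where the Gaussian intensity underflows to zero persons
  z <- matrix(0, 20, 20)
  z[hot["row"], hot["col"]] <- 3
  far <- if (hot["row"] > 10) 1 else 20
  z[far, c(1, 20)] <- c(1, 2)
  ch <- density_change(zone_density(p20, z), zone_density(p70, z))
  expect_equal(ch$change[ch$zone == 1], 0)
  expect_equal(ch$change[ch$zone == 2], 0)
  expect_gt(ch$change[ch$zone == 3], 0)
})

test_that("ground truth reacts to the shift as designed", {
  still <- small_scenario(seed = 16, shift_frac = 0, gcm_frac = 0)
  gt <- ground_truth_accounts(still)
  expect_equal(gt$account$decrease_pct, 0)
  expect_equal(gt$account$vu_year, Inf)
  expect_equal(gt$account$A1, 0)
  expect_equal(gt$account$A2, 0)
  # a shift far beyond every envelope width removes all suitability
  wiped <- small_scenario(seed = 16, shift_frac = 1, gcm_frac = 0)
  gtw <- ground_truth_accounts(wiped)
  expect_equal(gtw$account$decrease_pct, 100)
  expect_equal(gtw$account$A_fut, 0)
})

test_that("ground-truth zones obey the partition and area identities", {
  scn <- small_scenario(seed = 17)
  gt <- ground_truth_accounts(scn)
  cnt <- zone_counts(gt$zones)
  expect_equal(sum(cnt), length(gt$zones))
  expect_equal(gt$account$A_cur, gt$account$A1 + gt$account$A3)
  expect_equal(gt$account$A_cur / 3600, sum(gt$present_mask))
  expect_equal(gt$account$A_fut / 3600, sum(gt$future_mask))
})
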