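test_that("block aggregation sums fine cells and conserves totals", {
  expect_equal(aggregate_population(matrix(1, 60, 60), 60),
               matrix(3600, 1, 1))
  expect_equal(aggregate_population(matrix(0, 12, 12), 6), matrix(0, 2, 2))
  set.seed(61)
  fine <- matrix(rpois(120 * 180, 4), 120, 180)
  coarse <- aggregate_population(fine, 60)
  expect_equal(dim(coarse), c(2, 3))
  expect_identical(sum(coarse), sum(fine))
  expect_error(aggregate_population(matrix(1, 61, 60), 60), "divisible")
  expect_error(aggregate_population(matrix(-1, 6, 6), 3), "non-negative")
  expect_warning(agg <- aggregate_population(matrix(c(NA, rep(2, 35)), 6, 6), 6),
                 "missing fine cells")
  expect_equal(agg[1, 1], 70)
})

test_that("hand-checked block sums are exact", {
  fine <- matrix(1:16, 4, 4, byrow = TRUE)
  expect_equal(aggregate_population(fine, 2),
               matrix(c(1 + 2 + 5 + 6, 3 + 4 + 7 + 8,
                        9 + 10 + 13 + 14, 11 + 12 + 15 + 16), 2, 2, byrow = TRUE))
})

test_that("zone densities divide zone population by zone area", {
  z <- matrix(c(1, 0, 0, 3), 2, 2)
  pop <- matrix(c(7200, 100, 100, 3600), 2, 2)
  d <- zone_density(pop, z)
  expect_equal(d$density[d$zone == 1], 2)      # 7200 persons / 3600 km^2
  expect_equal(d$density[d$zone == 3], 1)
  expect_false(d$defined[d$zone == 2])         # empty zone: the diamond case
  expect_true(is.na(d$density[d$zone == 2]))
  # uniform population gives identical densities in non-empty zones
  z2 <- matrix(c(1, 2, 3, 3), 2, 2)
  du <- zone_density(matrix(1800, 2, 2), z2)
  expect_equal(du$density, rep(0.5, 3))
})

test_that("pooled density is the population-weighted mean of zone densities", {
  set.seed(62)
  z <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  pop <- matrix(rpois(64, 1000), 8, 8)
  d <- zone_density(pop, z)
  inz <- !is.na(z) & z > 0
  pooled <- sum(pop[inz]) / (sum(inz) * 3600)
  expect_equal(sum(d$persons) / sum(d$area_km2), pooled)
  expect_equal(stats::weighted.mean(d$density, d$area_km2), pooled)
})

test_that("density change subtracts epochs over fixed zone geometry", {
  z <- matrix(c(1, 2, 3, 0), 2, 2)
  d20 <- zone_density(matrix(c(360000, 360000, 360000, 0), 2, 2), z)
  d70 <- zone_density(matrix(c(507600, 360000, 212400, 0), 2, 2), z)
  ch <- density_change(d20, d70)
  expect_equal(ch$change, c(41, 0, -41))
  expect_true(all(ch$defined))
  # undefined zones propagate
  z2 <- matrix(c(1, 0, 3, 0), 2, 2)
  ch2 <- density_change(zone_density(matrix(0, 2, 2), z2),
                        zone_density(matrix(0, 2, 2), z2))
  expect_false(ch2$defined[ch2$zone == 2])
  expect_true(is.na(ch2$change[ch2$zone == 2]))
})

test_that("risk rows combine computed, derived and external flags", {
  # species losing its whole niche: empty zones 2 and 3
  z <- matrix(c(1, 1, 0, 0), 2, 2)
  acc <- species_account(z, "doomed", "rcp60")
  pop20 <- matrix(c(100, 100, 0, 0), 2, 2) * 3600
  pop70 <- matrix(c(80, 80, 0, 0), 2, 2) * 3600
  pr <- list(doomed = density_change(zone_density(pop20, z),
                                     zone_density(pop70, z)))
  ext <- data.frame(species = "doomed", population_trend = "decreasing",
                    trade_listed = TRUE)
  lim <- list(doomed = c("bio17", "bio17", "bio12"))
  r <- risk_matrix(acc, pr, ext, lim)
  expect_equal(r$decrease_suitable_niche, "+")
  expect_equal(r$population_decrease, "+")
  expect_equal(r$overexploitation_trade, "+")
  expect_equal(r$density_zone1, "-")
  expect_equal(r$density_zone2, "undefined")
  expect_equal(r$density_zone3, "undefined")
  # limited only by precipitation variables
  expect_equal(r$influence_precipitation, "+")
  expect_equal(r$influence_temperature, "-")
  # rendering maps the sentinels to the published glyphs
  glyphs <- render_risk_glyphs(r)
  expect_equal(glyphs$density_zone2, "♦")
  r_missing <- risk_matrix(acc, pr)
  expect_equal(r_missing$population_decrease, "unknown")
  expect_equal(render_risk_glyphs(r_missing)$population_decrease, "*")
})

test_that("risk flags are pure functions of their inputs", {
  z <- matrix(c(1, 2, 3, 3), 2, 2)
  acc <- species_account(z, "sp", "rcp60")
  pop <- matrix(3600, 2, 2)
  pr <- list(sp = density_change(zone_density(pop, z), zone_density(pop, z)))
  r1 <- risk_matrix(acc, pr, limiting = list(sp = c("bio1", "bio17")))
  r2 <- risk_matrix(acc, pr, limiting = list(sp = c("bio1", "bio17")))
  expect_identical(r1, r2)
  # zero density change everywhere gives all-negative density flags
  expect_equal(unlist(r1[c("density_zone1", "density_zone2", "density_zone3")],
                      use.names = FALSE), rep("-", 3))
  # both a temperature and a precipitation variable limit edge cells
  expect_equal(r1$influence_temperature, "+")
  expect_equal(r1$influence_precipitation, "+")
})
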