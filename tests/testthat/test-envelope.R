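test_that("fitting stores sorted per-variable training distributions", {
  m <- env_fit(cbind(bio1 = 9:1))
  expect_equal(m$values$bio1, 1:9)
  expect_equal(m$n_train, 9)
  two <- env_fit(cbind(bio1 = c(3, 1, 2), bio12 = c(10, 30, 20)))
  expect_equal(two$values, list(bio1 = c(1, 2, 3), bio12 = c(10, 20, 30)))
  expect_error(env_fit(cbind(bio1 = 1)), "two training rows")
  expect_error(env_fit(cbind(bio1 = c(1, NA))), "complete")
})

test_that("percentiles are tie-aware and clamp outside the training range", {
  m <- env_fit(cbind(bio1 = 1:9))
  expect_equal(env_percentile(m, "bio1", 5), 0.5)
  expect_equal(env_percentile(m, "bio1", 1), 0.5 / 9)
  expect_equal(env_percentile(m, "bio1", 0), 0)
  expect_equal(env_percentile(m, "bio1", 10), 1)
  expect_error(env_percentile(m, "bio99", 1), "unknown variable")
})

test_that("tied training values carry half weight", {
  # percentile at a duplicated value equals the tie-aware count either way
  # the duplicates are expressed
  dup <- env_fit(cbind(bio1 = c(1, 2, 2, 3)))
  expect_equal(env_percentile(dup, "bio1", 2), (1 + 0.5 * 2) / 4)
  rep3 <- env_fit(cbind(bio1 = rep(c(1, 2, 3), each = 3)))
  expect_equal(env_percentile(rep3, "bio1", 2), (3 + 0.5 * 3) / 9)
  expect_equal(env_percentile(rep3, "bio1", 2),
               env_percentile(env_fit(cbind(bio1 = c(1, 2, 3))), "bio1", 2))
})

test_that("scores fold the percentile and take the minimum across variables", {
  m <- env_fit(cbind(bio1 = 1:9))
  expect_equal(env_score(m, cbind(bio1 = 5)), 1)        # at the median
  expect_equal(env_score(m, cbind(bio1 = 2)), 1 / 3)    # 2 * 1.5/9
  expect_equal(env_score(m, cbind(bio1 = 0)), 0)        # below the minimum
  m2 <- env_fit(cbind(bio1 = 1:9, bio12 = seq(100, 900, by = 100)))
  # one variable outside its range forces zero regardless of the other
  expect_equal(env_score(m2, cbind(bio1 = 5, bio12 = 99)), 0)
  expect_equal(env_score(m2, cbind(bio1 = 5, bio12 = 500)), 1)
  expect_true(is.na(env_score(m2, cbind(bio1 = 5, bio12 = NA))))
})

test_that("degenerate constant variables score by exact match", {
  m <- env_fit(cbind(bio1 = c(7, 7, 7)))
  expect_equal(env_score(m, cbind(bio1 = 7)), 1)  # tie-aware median
  expect_equal(env_score(m, cbind(bio1 = 7.001)), 0)
})

test_that("scoring matches the brute-force counting oracle", {
  set.seed(31)
  for (case in 1:60) {
    n <- sample(2:20, 1); k <- sample(1:5, 1)
    train <- matrix(sample(0:30, n * k, replace = TRUE) / 3, n, k,
                    dimnames = list(NULL, paste0("bio", 1:k)))
    probe <- matrix(sample(-5:35, 8 * k, replace = TRUE) / 3, 8, k,
                    dimnames = list(NULL, paste0("bio", 1:k)))
    m <- env_fit(train)
    expect_equal(env_score(m, probe), oracle_score(train, probe),
                 tolerance = 1e-12)
  }
})

test_that("suitability decays monotonically away from the median percentile", {
  set.seed(32)
  train <- cbind(bio1 = rnorm(50))
  m <- env_fit(train)
  xs <- seq(-3, 3, length.out = 200)
  p <- env_percentile(m, "bio1", xs)
  s <- env_score(m, cbind(bio1 = xs))
  ord <- order(abs(p - 0.5))
  expect_true(all(diff(s[ord]) <= 1e-12))
})

test_that("every training point is inside its own envelope", {
  set.seed(33)
  train <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("bio1", "bio12")))
  m <- env_fit(train)
  s <- env_score(m, train)
  expect_true(all(s > 0))
  expect_true(all(binarize(s) == 1))
})

test_that("adding an interior training point never shrinks the envelope", {
  set.seed(34)
  for (i in 1:10) {
    train <- matrix(runif(30, 0, 10), 15, 2,
                    dimnames = list(NULL, c("bio1", "bio2")))
    probe <- matrix(runif(60, -2, 12), 30, 2,
                    dimnames = list(NULL, c("bio1", "bio2")))
    inner <- matrix(colMeans(train), 1, 2,
                    dimnames = list(NULL, c("bio1", "bio2")))
    before <- binarize(env_score(env_fit(train), probe))
    after <- binarize(env_score(env_fit(rbind(train, inner)), probe))
    expect_true(all(after >= before))
  }
})

test_that("binarization thresholds strictly at zero and keeps missingness", {
  expect_equal(binarize(c(0.0001, 0, 1, NA)), c(1, 0, 1, NA))
  z <- matrix(0, 3, 3)
  expect_equal(binarize(z), z)
})

test_that("models serialize to JSON and predict identically after reload", {
  g <- toy_grid(5, 5)
  set.seed(35)
  layers <- list(bio1 = matrix(rnorm(25), 5, 5),
                 bio12 = matrix(rexp(25, 1 / 300), 5, 5))
  st <- toy_stack(g, layers)
  train <- extract_values(st, random_points(g, 12, seed = 36))$values
  m <- env_fit(train)
  p <- withr::local_tempfile(fileext = ".json")
  env_write(m, p)
  m2 <- env_read(p)
  expect_equal(m2$values, m$values)
  expect_equal(predict(m2, st), predict(m, st))
})

test_that("prediction on a stack flags missing climate cells", {
  g <- toy_grid(3, 3)
  lay <- matrix(as.numeric(1:9), 3, 3)
  lay[2, 2] <- NA
  st <- toy_stack(g, lay)
  m <- env_fit(cbind(bio1 = c(2, 8)))
  s <- predict(m, st)
  expect_true(is.na(s[2, 2]))
  expect_equal(attr(s, "scenario"), "present")
  expect_error(predict(m, toy_stack(g, list(bio4 = lay))), "lacks model layer")
})

test_that("the limiting variable is the one at its envelope edge", {
  # temperature probes sit at the training median (folded score 1);
  # precipitation probes sit toward its envelope edge
  train <- cbind(bio1 = seq(-20, 40, by = 2), bio17 = seq(490, 510, length.out = 31))
  m <- env_fit(train)
  probe <- cbind(bio1 = rep(10, 4), bio17 = c(490.5, 494, 506, 509.5))
  expect_equal(env_limiting_variable(m, probe), rep("bio17", 4))
})
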