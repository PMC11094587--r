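test_that("euclidean_distance matches the sum-of-squares formula", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  v <- c(1.2, -3, 0.5)
  expect_identical(euclidean_distance(v, v), 0)
  set.seed(2)
  for (i in 1:20) {
    E <- sample(1:6, 1)
    a <- rnorm(E); b <- rnorm(E)
    expect_equal(euclidean_distance(a, b), sqrt(sum((a - b)^2)))
  }
  expect_error(euclidean_distance(1:3, 1:4), "length mismatch")
  expect_error(euclidean_distance(c(1, NA), c(1, 2)), "undefined")
})

test_that("simplex weights anchor the nearest neighbour at exp(-1)", {
  expect_equal(simplex_weights(c(1, 2, 4)), exp(-c(1, 2, 4)))
  expect_equal(simplex_weights(rep(0.7, 5)), rep(exp(-1), 5))
  set.seed(3)
  for (i in 1:50) {
    # distance ratios kept below ~100 so the exponential cannot underflow
    d <- sort(runif(sample(2:8, 1), 0.1, 10))
    w <- simplex_weights(d)
    expect_equal(w[1], exp(-1))
    expect_true(all(diff(w) <= 0))          # non-increasing with rank
    expect_true(all(w > 0 & w <= 1))
  }
})

test_that("zero nearest distance falls back to the documented limit", {
  expect_equal(simplex_weights(c(0, 0, 2, 4)),
               c(1, 1, exp(-1), exp(-2)))
  expect_equal(simplex_weights(c(0, 0, 0)), rep(1, 3))
  expect_error(simplex_weights(numeric(0)), "no distances")
  expect_error(simplex_weights(c(2, 1)), "ranked ascending")
  expect_error(simplex_weights(c(-1, 1)), "non-negative")
})

test_that("neighbour ranking agrees with a brute-force sort", {
  set.seed(4)
  for (i in 1:15) {
    T <- sample(20:40, 1)
    E <- sample(1:4, 1)
    N <- rnorm(T)
    lag <- edm_embed(N, E)
    ts <- sample(valid_focal_times(T, E), 1)
    lib <- construct_library(lag, ts)
    k <- min(E + 1L, lib$size)
    nb <- rank_neighbours(lag, lib, ts, k)
    orc <- oracle_simplex(first_difference(N), E, ts, lib$member_times, k)
    expect_identical(nb$times, orc$psi)
    expect_equal(nb$distances, orc$d)
    expect_true(!is.unsorted(nb$distances))
  }
})

test_that("an exact duplicate of the focal point ranks first at distance 0", {
  # periodic data guarantee exact duplicates of every delay vector
  N <- periodic_series(c(1, 5, 2, 4, 3), reps = 5)
  lag <- edm_embed(N, 2)
  lib <- construct_library(lag, 12)
  nb <- rank_neighbours(lag, lib, 12, 3)
  expect_identical(nb$distances[1], 0)
  expect_equal(nb$weights[1], 1)
  # tie-break: equal distances resolve by ascending time index
  zero_times <- nb$times[nb$distances == 0]
  expect_identical(zero_times, sort(zero_times))
})

test_that("rank_neighbours errors when the library is smaller than k", {
  lag <- edm_embed(rnorm(12), 4)
  lib <- construct_library(lag, 6)
  expect_error(rank_neighbours(lag, lib, 6, lib$size + 1L),
               "C = \\d+ candidates but k")
})

test_that("predict_point reproduces the weighted-average formula", {
  set.seed(6)
  for (i in 1:15) {
    T <- sample(25:50, 1)
    E <- sample(1:4, 1)
    N <- rnorm(T)
    lag <- edm_embed(N, E)
    ts <- sample(valid_focal_times(T, E), 1)
    pr <- predict_point(lag, ts)
    orc <- oracle_simplex(first_difference(N), E, ts,
                          oracle_library(T, E, ts))
    expect_equal(pr$y_hat, orc$y_hat)
    # convexity: within neighbour-target range and the whole-series range
    targets <- lag$Y[pr$neighbours$times + 1L]
    expect_gte(pr$y_hat, min(targets))
    expect_lte(pr$y_hat, max(targets))
    expect_gte(pr$y_hat, min(lag$Y))
    expect_lte(pr$y_hat, max(lag$Y))
    # the level-scale prediction is the undifferenced value
    expect_equal(pr$n_hat, pr$y_hat + N[ts + 1L])
  }
})

test_that("prediction is exact when all neighbours map to the same target", {
  # construct differences where several distinct states all move to 7
  Y <- c(1, 7, 2, 7, 3, 7, 4, 7, 5, 7, 6, 7, 1.5, 7, 2.5)
  lag <- edm_embed(c(0, cumsum(Y)), 1)
  expect_identical(lag$Y, Y)   # the integer-and-half values are exact
  # focal at an odd index: all odd-index states move to Y = 7
  pr <- predict_point(lag, 5)
  nb_targets <- Y[pr$neighbours$times + 1L]
  expect_true(all(nb_targets == 7))
  expect_identical(pr$y_hat, 7)
})

test_that("simplex predictions are deterministic", {
  N <- generate_spiky_series(spiky_series_config(T = 60, seed = 8))
  a <- predict_point(edm_embed(N, 3), 20)
  b <- predict_point(edm_embed(N, 3), 20)
  expect_identical(a$y_hat, b$y_hat)
  expect_identical(a$neighbours$times, b$neighbours$times)
})

test_that("forecast_next forecasts one step past the data", {
  # a strictly periodic series is forecast exactly (all nearest neighbours
  # are exact state matches)
  block <- c(0.5, 2.1, 0.9, 3.3, 1.2, 0.7)
  N <- periodic_series(block, reps = 10)   # enough exact state matches that
                                           # all E + 1 neighbours have d = 0
  fc <- forecast_next(N, E = 6)
  expect_equal(fc$n_hat, block[1 + length(N) %% length(block)])
  expect_false(fc$remedy_applied)

  # clamp remedy replaces a negative level forecast by the observed minimum
  set.seed(21)
  found <- FALSE
  for (seed in 1:30) {
    s <- generate_spiky_series(spiky_series_config(T = 50, seed = seed))
    raw <- forecast_next(s, 3, remedy = "none")
    if (raw$n_hat < 0) {
      clamped <- forecast_next(s, 3, remedy = "clamp_to_min")
      expect_identical(clamped$n_hat, min(s))
      expect_true(clamped$remedy_applied)
      found <- TRUE
      break
    }
  }
  expect_true(found)   # at least one negative forecast among 30 seeds

  expect_error(forecast_next(c(-1, 2, 3, 4, 5, 6, 7, 8), 2,
                             remedy = "log_transform"),
               "strictly positive")
})

test_that("log-transform remedy back-transforms a positive forecast", {
  s <- generate_spiky_series(spiky_series_config(T = 60, seed = 3))
  fc <- forecast_next(s, 3, remedy = "log_transform")
  expect_gt(fc$n_hat, 0)
  # matches running the pipeline on the log series by hand
  manual <- forecast_next(log(s), 3, remedy = "none")
  expect_identical(fc$n_hat, exp(manual$n_hat))
})
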