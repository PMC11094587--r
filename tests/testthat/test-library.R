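test_that("valid focal times match the index formulas and the oracle", {
  expect_identical(valid_focal_times(50, 8), 8:48)
  expect_identical(valid_focal_times(50, 2), 2:48)
  expect_identical(valid_focal_times(50, 2, "forecast"), 2:49)

  # T = 8, E = 3: brute-force check that each member time has a defined
  # vector and a known next difference
  vt <- valid_focal_times(8, 3)
  expect_identical(vt, 3:6)
  for (ts in vt) {
    expect_true(all((ts - 0:2) >= 1 & (ts - 0:2) <= 7))  # x_{t*} defined
    expect_true(ts + 1 <= 7)                             # Y_{t*+1} known
  }
  expect_error(valid_focal_times(4, 3), "too short")
})

test_that("library membership matches the crossing-out oracle exhaustively", {
  for (T in seq(10, 30, by = 4)) {
    set.seed(T)
    lagc <- lapply(1:6, function(E) {
      if (E <= T - 2) edm_embed(rnorm(T), E) else NULL
    })
    for (E in 1:6) {
      if (E > T - 2) next
      tstars <- valid_focal_times(T, E)
      want <- lapply(tstars, function(ts) oracle_library(T, E, ts))
      got <- lapply(tstars, function(ts) {
        if (length(want[[match(ts, tstars)]]) == 0L) {
          expect_error(construct_library(lagc[[E]], ts), "empty")
          integer(0)
        } else {
          construct_library(lagc[[E]], ts)$member_times
        }
      })
      expect_identical(got, want, label = sprintf("T=%d E=%d", T, E))
    }
  }
})

test_that("end-of-series libraries match the closed-form sets", {
  T <- 50
  set.seed(1)
  for (E in c(2, 3, 5)) {
    lag <- edm_embed(rnorm(T), E)
    # first overlap of the condition-(d) window with the series end
    lib <- construct_library(lag, T - E - 1L)
    expect_identical(lib$member_times, seq.int(E, T - E - 2L))
    # last valid focal time
    lib2 <- construct_library(lag, T - 2L)
    expect_identical(lib2$member_times, seq.int(E, T - 3L))
    # forecast mode: all rows with defined successors, focal excluded
    lib3 <- construct_library(lag, T - 1L, purpose = "forecast")
    expect_identical(lib3$member_times, seq.int(E, T - 2L))
  }
})

test_that("closed-form size equals the constructive count on a grid", {
  for (T in seq(10, 60, by = 2)) {
    set.seed(T)
    s <- rnorm(T)
    for (E in 1:8) {
      if (E > T - 2) next
      lag <- edm_embed(s, E)
      tstars <- valid_focal_times(T, E)
      formula <- vapply(tstars, function(ts) library_size(T, E, ts),
                        integer(1))
      oracle <- vapply(tstars, function(ts) length(oracle_library(T, E, ts)),
                       integer(1))
      constructive <- vapply(tstars, function(ts) {
        tryCatch(construct_library(lag, ts)$size, error = function(e) 0L)
      }, integer(1))
      expect_identical(formula, oracle, label = sprintf("T=%d E=%d", T, E))
      expect_identical(constructive, oracle,
                       label = sprintf("T=%d E=%d", T, E))
    }
  }
})

test_that("size is constant then climbs by one per step to C_E + E", {
  T <- 50L
  for (E in c(2L, 3L, 8L)) {
    sizes <- vapply(valid_focal_times(T, E),
                    function(ts) library_size(T, E, ts), integer(1))
    CE <- T - 2L * (E + 1L)
    flat <- seq_len(T - 2L * E - 1L)       # t* = E .. T-E-2
    expect_true(all(sizes[flat] == CE))
    expect_identical(diff(sizes[-flat]), rep(1L, E - 1L))
    expect_identical(sizes[length(sizes)], CE + E)
  }
  # for fixed t* in the constant region, C drops by exactly 2 per unit E
  for (E in 2:7) {
    expect_identical(library_size(50, E + 1L, 20) - library_size(50, E, 20),
                     -2L)
  }
})

test_that("radius policy replaces condition (d) and contains the default", {
  T <- 24
  set.seed(5)
  s <- rnorm(T)
  for (E in c(2, 4)) {
    lag <- edm_embed(s, E)
    for (ts in valid_focal_times(T, E)) {
      def <- construct_library(lag, ts)$member_times
      r0 <- construct_library(lag, ts, exclusion_policy("radius", 0L))$member_times
      expect_true(all(def %in% r0))
      expect_identical(r0, oracle_library(T, E, ts, mode = "radius",
                                          radius_k = 0L))
      rE <- construct_library(lag, ts, exclusion_policy("radius", E))$member_times
      expect_identical(rE, oracle_library(T, E, ts, mode = "radius",
                                          radius_k = E))
      # radius k excludes symmetrically around t*
      expect_false(any(abs(rE - ts) <= E))
    }
  }
})

test_that("policies and the size grid validate their inputs", {
  expect_error(exclusion_policy("radius", -1), "non-negative")
  expect_error(edmforecast:::as_policy("bogus"), "unrecognised")
  expect_identical(edmforecast:::as_policy("radius:3")$radius_k, 3L)
  expect_error(library_size(50, 2, 49), "invalid")
  expect_identical(library_size(50, 2, 49, purpose = "forecast"), 47L)

  grid <- library_size_grid(50, 3)
  expect_identical(grid$E2[10], 44L)
  expect_true(is.na(grid$E3[2]))
  expect_true(is.na(grid$E2[49]))
})

test_that("without differencing the index formulas shift by one", {
  T <- 20
  set.seed(9)
  lag <- edm_embed(rnorm(T), 3, differencing = "none")
  # L = T, so the evaluation window is {E .. T-1} and libraries use the
  # same rules driven by defined flags
  lib <- construct_library(lag, 10)
  expect_identical(lib$member_times,
                   oracle_library(T, 3, 10, L = T))
  lib_end <- construct_library(lag, T - 1L)
  expect_identical(lib_end$member_times,
                   oracle_library(T, 3, T - 1L, L = T))
})
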