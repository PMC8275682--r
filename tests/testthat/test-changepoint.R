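test_that("trivial penalty limits: constant series and dominating penalty", {
  expect_equal(pelt_mean(rep(3, 30), penalty = 1, min_segment_length = 2)$m, 0)
  x <- rnorm(40)
  # a penalty at least the unsegmented cost can never be worth paying
  expect_equal(pelt_mean(x, penalty = 1e9, min_segment_length = 2)$m, 0)
  expect_equal(aic_penalty(), 4)
  expect_equal(aic_penalty(rnorm(10)), 4)   # independent of the series
  expect_equal(aic_penalty(k = 3), 6)
})

test_that("a clean 4-sd step is split exactly once at the step", {
  x <- c(rep(0, 10), rep(8, 10))
  seg <- pelt_mean(x, penalty = 2, min_segment_length = 2)
  expect_equal(seg$changepoints, 10L)
  expect_equal(seg$segment_means, c(0, 8))
  # exhaustive oracle agrees
  ex <- exhaustive_segmentation(x, penalty = 2, min_segment_length = 2,
                                max_m = 3)
  expect_equal(ex$changepoints, seg$changepoints)
  expect_equal(ex$total_cost, seg$total_cost)
})

test_that("PELT equals exhaustive enumeration on random planted-shift series", {
  set.seed(101)
  for (i in 1:120) {
    n <- sample(20:40, 1)
    L <- sample(7:9, 1)   # full enumeration stays feasible (no m cap)
    shift <- sample(c(-5, -3, 0, 3, 5), 1)
    k <- sample(seq(L, n - L), 1)
    x <- rnorm(n) + c(rep(0, k), rep(shift, n - k))
    p <- pelt_mean(x, penalty = 4, min_segment_length = L)
    e <- exhaustive_segmentation(x, penalty = 4, min_segment_length = L)
    expect_equal(p$total_cost, e$total_cost, tolerance = 1e-8)
    expect_identical(p$changepoints, e$changepoints)
  }
})

test_that("the number of changepoints is non-increasing in the penalty", {
  set.seed(7)
  x <- rnorm(49) + rep(c(0, 4, 0, 4), c(13, 12, 12, 12))
  ms <- vapply(c(0.5, 1, 2, 4, 8, 16, 64, 1e6),
               function(p) pelt_mean(x, p, min_segment_length = 5)$m,
               integer(1))
  expect_true(all(diff(ms) <= 0))
})

test_that("segmentation invariants hold: partition, means, penalized cost", {
  set.seed(12)
  x <- rnorm(49) + rep(c(0, 5), c(24, 25))
  seg <- pelt_mean(x, penalty = 4, min_segment_length = 10, years = 1970:2018)
  expect_equal(seg$segment_first_year[1], 1970)
  expect_equal(seg$segment_last_year[seg$m + 1], 2018)
  expect_true(all(seg$segment_last_year - seg$segment_first_year + 1 >= 10))
  for (k in seq_len(seg$m + 1)) {
    ix <- which(1970:2018 >= seg$segment_first_year[k] &
                  1970:2018 <= seg$segment_last_year[k])
    expect_equal(seg$segment_means[k], mean(x[ix]))
  }
  expect_equal(seg$total_cost, sum(seg$segment_costs) + seg$m * seg$penalty)
})

test_that("planted regime boundaries are recovered on synthetic series", {
  hits <- 0L
  for (s in 1:50) {
    tab <- simulate_regime_series(four_regime_spec(s))
    seg <- pelt_mean(tab$ssb, penalty = 4, min_segment_length = 10,
                     years = tab$year)
    if (seg$m == 3 && all(abs(seg$changepoint_years -
                                c(1982, 1994, 2006)) <= 1)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 50, 0.9)
})

test_that("productivity shifts planted earlier than biomass are found earlier", {
  # plant the productivity (R/SSB) drop two years before the SSB drop
  spec_ssb_years <- c(1996)
  for (s in 1:5) {
    set.seed(s)
    years <- 1970:2018
    ssb <- c(rep(40, 27), rep(18, 22)) + rnorm(49, 0, 1.5)       # drop 1997
    prod <- c(rep(0.9, 25), rep(0.35, 24)) + rnorm(49, 0, 0.025) # drop 1995
    seg_ssb <- pelt_mean(ssb, 4, 10, years = years)
    seg_prod <- pelt_mean(prod, 4, 10, years = years)
    expect_lt(seg_prod$changepoint_years[1], seg_ssb$changepoint_years[1])
  }
})

test_that("input validation: short series, non-finite values, oracle guard", {
  expect_error(pelt_mean(rnorm(5), 4, min_segment_length = 10),
               "no admissible segmentation")
  expect_error(pelt_mean(c(1, NA, 3, 4), 4, 2), "non-finite")
  expect_error(exhaustive_segmentation(rnorm(80), 4, 3, max_m = 5),
               "refused")
})
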