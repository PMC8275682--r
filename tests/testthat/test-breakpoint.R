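test_that("a perfect single-regime relationship selects zero breaks", {
  x <- seq_len(30)
  y <- 2 + 0.5 * x
  per_m <- dp_breakpoints(y, x, 2L, 5L)
  expect_true(all(vapply(per_m, `[[`, numeric(1), "rss") < 1e-18))
  expect_equal(select_num_breaks(per_m, 30)$m, 0L)
})

test_that("a zero-noise slope reversal is located exactly", {
  x <- as.numeric(1:30)
  y <- c(x[1:15], -x[16:30] + 31)   # slopes +1 then -1, no shared point
  per_m <- dp_breakpoints(y, x, 2L, 5L)
  sel <- select_num_breaks(per_m, 30)
  expect_equal(sel$m, 1L)
  expect_equal(per_m[["m1"]]$breaks, 15L)
  tab <- stock_series(2001:2030, ssb = pmax(y, 0.1), recruitment = rep(1, 30),
                      f = rep(1, 30), sst = x)
  fit <- fit_breakpoint(tab, "ssb", "sst", max_breaks = 2, min_segment = 5)
  expect_equal(fit$m, 1L)
  expect_equal(fit$break_years, 2015L)
  expect_equal(vapply(fit$regimes, `[[`, numeric(1), "slope"), c(1, -1),
               tolerance = 1e-8)
})

test_that("the dynamic program equals exhaustive enumeration with monotone RSS", {
  set.seed(202)
  for (i in 1:80) {
    n <- sample(20:40, 1)
    L <- sample(4:6, 1)
    x <- rnorm(n)
    y <- x + rnorm(n) * 0.5
    if (i %% 2 == 0) {
      k <- sample(seq(L, n - L), 1)
      y[(k + 1):n] <- -x[(k + 1):n] + rnorm(n - k) * 0.5
    }
    d <- dp_breakpoints(y, x, 2L, L)
    e <- exhaustive_breakpoints(y, x, 2L, L)
    rss_d <- vapply(d, `[[`, numeric(1), "rss")
    expect_equal(rss_d, vapply(e, `[[`, numeric(1), "rss"),
                 tolerance = 1e-8)
    expect_true(all(diff(rss_d) <= 1e-10))
  }
})

test_that("BIC keeps the no-break model on single-regime Gaussian data", {
  keep0 <- 0L
  for (s in 1:200) {
    set.seed(s)
    x <- rnorm(40)
    y <- 1 + 0.5 * x + rnorm(40, 0, 0.5)
    per_m <- dp_breakpoints(y, x, 2L, 6L)
    if (select_num_breaks(per_m, 40)$m == 0L) keep0 <- keep0 + 1L
  }
  expect_gte(keep0 / 200, 0.9)
})

test_that("identical RSS for consecutive m selects the smaller m", {
  fake <- list(m0 = list(m = 0L, breaks = integer(0), rss = 4),
               m1 = list(m = 1L, breaks = 10L, rss = 4))
  expect_equal(select_num_breaks(fake, 30)$m, 0L)
})

test_that("breaks follow time order, not covariate order", {
  set.seed(9)
  x <- rnorm(30)
  y <- c(2 * x[1:15], -2 * x[16:30]) + rnorm(30, 0, 0.1)
  ord <- order(x)
  d_time <- dp_breakpoints(y, x, 1L, 5L)
  d_perm <- dp_breakpoints(y[ord], x[ord], 1L, 5L)
  expect_false(isTRUE(all.equal(d_time[["m1"]]$rss, d_perm[["m1"]]$rss)))
})

test_that("six default relationships yield six fits, equivariant to scaling", {
  tab <- make_tipping_fixture(seed = 3)
  fits <- fit_relationships(tab, analysis_config())
  expect_length(fits, 6)
  expect_named(fits, c("ssb~f", "ssb~scaled_pressure", "recruitment~ssb",
                       "recruitment~sst", "productivity~ssb",
                       "productivity~sst"))
  # affine rescaling of the covariate transforms coefficients, not breaks
  f1 <- fit_breakpoint(tab, "recruitment", "sst")
  tab2 <- tab
  tab2$sst <- 2 * tab2$sst + 10
  f2 <- fit_breakpoint(tab2, "recruitment", "sst")
  expect_identical(f1$break_years, f2$break_years)
  s1 <- vapply(f1$regimes, `[[`, numeric(1), "slope")
  s2 <- vapply(f2$regimes, `[[`, numeric(1), "slope")
  expect_equal(s1, 2 * s2, tolerance = 1e-8)
})

test_that("infeasible and misconfigured requests error cleanly", {
  expect_error(dp_breakpoints(rnorm(10), rnorm(10), 3L, 5L), "infeasible")
  expect_error(dp_breakpoints(rnorm(10), rnorm(10), 1L, 1L), "min_segment")
  tab <- make_tipping_fixture(seed = 3)
  expect_error(fit_breakpoint(tab, "ssb", "salinity"), "unknown variable")
  expect_error(exhaustive_breakpoints(rnorm(80), rnorm(80), 2L, 5L),
               "refused")
  # constant covariate within a regime falls back to intercept-only
  tabc <- stock_series(2001:2020, ssb = rnorm(20, 50, 2),
                       recruitment = rep(10, 20), f = rep(1, 20),
                       sst = rep(8, 20))
  expect_warning(fit_breakpoint(tabc, "ssb", "sst", max_breaks = 0,
                                min_segment = 5),
                 "constant covariate")
})
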