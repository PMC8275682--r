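test_that("regime simulator hits its means exactly at zero noise", {
  spec <- regime_spec(1970, 49, boundaries = c(1983, 1995, 2007),
                      means = list(ssb = c(40, 20, 36, 16),
                                   recruitment = c(30, 14, 26, 10),
                                   f = c(1, 1, 1, 1)),
                      noise_sd = list(ssb = 0, recruitment = 0, f = 0),
                      sst_noise_sd = 0, seed = 1)
  tab <- simulate_regime_series(spec)
  expect_equal(unique(tab$ssb[tab$year < 1983]), 40)
  expect_equal(unique(tab$ssb[tab$year >= 2007]), 16)
  expect_equal(unique(tab$recruitment[tab$year %in% 1983:1994]), 14)
  # SST is the exact trend
  expect_equal(tab$sst, spec$sst_start + spec$sst_trend * (tab$year - 1970))
})

test_that("generators are pure functions of their spec (seed included)", {
  expect_identical(simulate_regime_series(four_regime_spec(11)),
                   simulate_regime_series(four_regime_spec(11)))
  expect_identical(make_tipping_fixture(5), make_tipping_fixture(5))
  expect_identical(sample_cusp_stationary(0.5, 1, 100, seed = 3),
                   sample_cusp_stationary(0.5, 1, 100, seed = 3))
})

test_that("regimes shorter than the minimum segment length are rejected", {
  expect_error(
    regime_spec(1970, 49, boundaries = c(1975, 1995, 2007),
                means = list(ssb = c(1, 1, 1, 1), recruitment = c(1, 1, 1, 1),
                             f = c(1, 1, 1, 1)),
                noise_sd = list(ssb = 0, recruitment = 0, f = 0)),
    "shorter than the minimum segment length")
})

test_that("stationary sampler matches symmetry, mode and quadrature density", {
  s <- sample_cusp_stationary(0, 3, 1e5, seed = 1)
  expect_lt(abs(mean(s)), 3 * sd(s) / sqrt(1e5))
  # single deep well at alpha=5, beta=0: mode near 5^(1/3)
  s2 <- sample_cusp_stationary(5, 0, 1e5, seed = 2)
  dens <- density(s2)
  expect_lt(abs(dens$x[which.max(dens$y)] - 5^(1 / 3)), 0.1)
  # goodness of fit against the numerically integrated density, 1% level
  ks <- suppressWarnings(
    stats::ks.test(sample_cusp_stationary(0, 3, 5000, seed = 3),
                   cusp_numeric_cdf(0, 3)))
  expect_gt(ks$p.value, 0.01)
})

test_that("cusp SDE decays deterministically and matches the stationary law", {
  tr <- simulate_cusp_sde(0, -2, sigma_z = 1e-9, dt = 1e-3, n_steps = 3000,
                          burn_in = 0, z0 = 1, seed = 1)
  expect_true(all(diff(tr[, 1]) < 1e-12))
  expect_lt(abs(tr[3000, 1]), 0.01)
  # long-run law at sigma_z = sqrt(2) equals the canonical density;
  # independent chains give clean i.i.d. draws for the KS test
  fin <- simulate_cusp_sde(0, 2, sigma_z = sqrt(2), dt = 2e-3, n_steps = 1,
                           burn_in = 4000, n_chains = 2000,
                           z0 = rnorm(2000), seed = 4)
  ks <- suppressWarnings(stats::ks.test(fin[1, ], cusp_numeric_cdf(0, 2)))
  expect_gt(ks$p.value, 0.01)
  # symmetric double well: both basins occupied about equally
  expect_lt(abs(mean(fin[1, ] > 0) - 0.5), 0.05)
  expect_error(simulate_cusp_sde(0, 2, sigma_z = 1, dt = 10, n_steps = 10,
                                 burn_in = 0, z0 = 3, seed = 1),
               "smaller dt")
})

test_that("stationary sampler and SDE agree in distribution", {
  a <- sample_cusp_stationary(0.4, 1.5, 1e4, seed = 6)
  b <- simulate_cusp_sde(0.4, 1.5, sigma_z = sqrt(2), dt = 2e-3, n_steps = 1,
                         burn_in = 4000, n_chains = 1e4, z0 = rnorm(1e4),
                         seed = 7)[1, ]
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("tipping fixture carries the planted pressure regime and geometry", {
  tab <- make_tipping_fixture(seed = 7)
  expect_equal(nrow(tab), 49)
  expect_identical(tab$year, 1970:2018)
  # regime-2 analogue (1986-1993): F mostly above 1.0
  expect_gt(mean(tab$f[tab$year %in% 1986:1993] > 1), 0.75)
  expect_gt(cor(tab$year, tab$sst), 0.9)                 # warming trend
  expect_lt(mean(tab$ssb[tab$year >= 2014]), mean(tab$ssb))  # late low state
  # byte-identical CSV under a fixed seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_stock_csv(make_tipping_fixture(9), p1)
  write_stock_csv(make_tipping_fixture(9), p2)
  expect_identical(readLines(p1), readLines(p2))
})
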