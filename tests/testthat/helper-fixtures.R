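# shared fixture builders (everything generated in code; no stored data)

tiny_stock_csv <- function(path, years = 2000:2002, ssb = c(10, 20, 40),
                           recruitment = c(5, 5, 10), f = c(1, 1, 1),
                           sst = c(8, 8.1, 8.2)) {
  utils::write.csv(data.frame(year = years, ssb = ssb,
                              recruitment = recruitment, f = f, sst = sst),
                   path, row.names = FALSE, quote = FALSE)
  path
}

four_regime_spec <- function(seed, noise_frac = 0.05) {
  means <- list(ssb = c(40, 20, 36, 16), recruitment = c(30, 14, 26, 10),
                f = c(0.9, 1.3, 1.0, 0.8))
  regime_spec(1970, 49, boundaries = c(1983, 1995, 2007), means = means,
              noise_sd = list(ssb = noise_frac * 40,
                              recruitment = noise_frac * 30,
                              f = noise_frac * 1),
              sst_start = 7.4, sst_trend = 0.035, sst_noise_sd = 0.15,
              seed = seed)
}

# observations from the cusp measurement model as an analysis-ready table
cusp_sim_table <- function(coef, x1, x2, seed) {
  spec <- cusp_sim_spec(coef[1], coef[2], coef[3], coef[4], coef[5], coef[6],
                        x1, x2, seed = seed)
  sim <- simulate_cusp_series(spec)
  list(table = data.frame(year = seq_along(x1), ssb = sim$state,
                          scaled_pressure = sim$asym, sst = sim$bifur),
       truth = sim)
}

# numeric CDF of the canonical stationary density, for goodness-of-fit
cusp_numeric_cdf <- function(alpha, beta) {
  function(q) {
    vapply(q, function(qq) {
      stats::integrate(function(z) cusp_stationary_density(z, alpha, beta),
                       -Inf, qq, rel.tol = 1e-9)$value
    }, numeric(1))
  }
}
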