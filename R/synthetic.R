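#' @title Synthetic stock series and cusp-process generators
#'
#' @description
#' Fixture generators with the statistical structure the analysis stages
#' assume: piecewise-constant regime means for the changepoint stage,
#' cusp-process observations for the catastrophe stage, and a packaged
#' 49-year "tipping" table that carries the full qualitative geometry
#' (early bistable years, late stable years at low biomass) through the
#' whole pipeline.  All generators are pure functions of their spec,
#' seed included.
#'
#' @name synthetic_data
NULL

#' Specification of a regime-structured annual series
#'
#' @param start_year first calendar year.
#' @param n_years series length in years.
#' @param boundaries first years of regimes 2, 3, ... (strictly increasing,
#'   inside the year span); empty for a single regime.
#' @param means named list of per-regime mean vectors, one per variable
#'   (`ssb`, `recruitment`, `f`), each of length `length(boundaries) + 1`.
#' @param noise_sd named list of Gaussian noise standard deviations, one
#'   scalar per variable.
#' @param sst_start,sst_trend,sst_noise_sd SST intercept (deg C at the first
#'   year), linear trend (deg C per year) and noise sd.
#' @param min_segment_length every regime must span at least this many years.
#' @param seed integer seed.
#' @return a `regime_spec` list.
#' @export
regime_spec <- function(start_year = 1970L, n_years = 49L,
                        boundaries = integer(0),
                        means, noise_sd,
                        sst_start = 7.5, sst_trend = 0.03, sst_noise_sd = 0.2,
                        min_segment_length = 10L, seed = 1L) {
  boundaries <- as.integer(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("regime spec error: boundaries must be strictly increasing",
         call. = FALSE)
  }
  years <- seq.int(start_year, length.out = n_years)
  if (length(boundaries) > 0 &&
      (min(boundaries) <= start_year || max(boundaries) > max(years))) {
    stop("regime spec error: boundaries outside the year span", call. = FALSE)
  }
  firsts <- c(start_year, boundaries)
  lens <- diff(c(firsts, max(years) + 1L))
  if (any(lens < min_segment_length)) {
    stop("regime spec error: regime of length ", min(lens),
         " is shorter than the minimum segment length ", min_segment_length,
         call. = FALSE)
  }
  k <- length(firsts)
  for (v in c("ssb", "recruitment", "f")) {
    if (length(means[[v]]) != k) {
      stop("regime spec error: means$", v, " must have one value per regime (",
           k, ")", call. = FALSE)
    }
    if (any(means[[v]] <= 0) || noise_sd[[v]] < 0) {
      stop("regime spec error: means must be positive, sds non-negative",
           call. = FALSE)
    }
  }
  structure(list(start_year = start_year, n_years = n_years,
                 boundaries = boundaries, means = means, noise_sd = noise_sd,
                 sst_start = sst_start, sst_trend = sst_trend,
                 sst_noise_sd = sst_noise_sd,
                 min_segment_length = as.integer(min_segment_length),
                 seed = as.integer(seed)),
            class = "regime_spec")
}

#' Simulate a regime-structured stock series
#'
#' Each variable is its per-regime mean plus i.i.d. Gaussian noise; SST is a
#' linear trend plus noise.  Values are floored at a tiny positive constant
#' so rare deep noise excursions cannot violate the positivity invariant.
#'
#' @param spec a [regime_spec()].
#' @return a validated `stock_series`.
#' @export
simulate_regime_series <- function(spec) {
  stopifnot(inherits(spec, "regime_spec"))
  set.seed(spec$seed)
  years <- seq.int(spec$start_year, length.out = spec$n_years)
  regime_of <- findInterval(years, c(spec$start_year, spec$boundaries))
  draw <- function(v) {
    pmax(spec$means[[v]][regime_of] +
           stats::rnorm(spec$n_years, 0, spec$noise_sd[[v]]), 1e-6)
  }
  sst <- spec$sst_start + spec$sst_trend * (years - spec$start_year) +
    stats::rnorm(spec$n_years, 0, spec$sst_noise_sd)
  stock_series(years, draw("ssb"), draw("recruitment"), draw("f"), sst)
}

#' Draw from the canonical cusp stationary density
#'
#' I.i.d. samples from \eqn{f(z) \propto \exp(\alpha z + \beta z^2/2 -
#' z^4/4)} by inverse-CDF interpolation on a fine grid (2^14 points) spanning
#' all equilibria plus wide quartic tails.  Rejection sampling is avoided
#' because its acceptance rate is unbounded below for extreme \eqn{\beta}.
#'
#' @param alpha asymmetry value.
#' @param beta bifurcation value.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @param ngrid grid resolution (default `2^14`).
#' @return numeric vector of n draws.
#' @export
sample_cusp_stationary <- function(alpha, beta, n, seed = NULL,
                                   ngrid = 2^14) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  eq <- cusp_equilibria(alpha, beta)
  lo <- min(eq$z) - 6
  hi <- max(eq$z) + 6
  zg <- seq(lo, hi, length.out = ngrid)
  g <- alpha * zg + beta * zg^2 / 2 - zg^4 / 4
  w <- exp(g - max(g))
  cdf <- cumsum(w)
  cdf <- cdf / cdf[ngrid]
  u <- stats::runif(n)
  # strictly increasing cdf copy for interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], zg[keep], xout = u, rule = 2)$y
}

#' Euler--Maruyama simulation of the cusp SDE
#'
#' Simulates \eqn{dz = (-z^3 + \beta z + \alpha)\,dt + \sigma_z\,dW} with a
#' fixed step.  With \eqn{\sigma_z = \sqrt{2}} the stationary law equals the
#' canonical density that [sample_cusp_stationary()] draws from; in general
#' the stationary law is \eqn{\propto \exp(2(\alpha z + \beta z^2/2 -
#' z^4/4)/\sigma_z^2)}.
#'
#' @param alpha,beta drift parameters.
#' @param sigma_z diffusion scale (> 0).
#' @param dt step size (default 1e-3).
#' @param n_steps steps to record after burn-in.
#' @param burn_in discarded initial steps (default 1e5 for a single chain,
#'   applies per chain).
#' @param n_chains independent chains simulated in parallel (vectorized).
#' @param z0 initial state, scalar or vector of length `n_chains`.
#' @param seed optional integer seed.
#' @return matrix `n_steps x n_chains` of recorded states.
#' @export
simulate_cusp_sde <- function(alpha, beta, sigma_z = sqrt(2), dt = 1e-3,
                              n_steps = 1000L, burn_in = 1e5, n_chains = 1L,
                              z0 = 0, seed = NULL) {
  stopifnot(sigma_z > 0, dt > 0, n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  z <- rep_len(z0, n_chains)
  sdt <- sqrt(dt)
  step <- function(z) {
    z + (-z^3 + beta * z + alpha) * dt +
      sigma_z * sdt * stats::rnorm(length(z))
  }
  for (i in seq_len(burn_in)) {
    z <- step(z)
    if (any(!is.finite(z))) {
      stop("numerical-stability error: non-finite state at burn-in step ", i,
           "; use a smaller dt", call. = FALSE)
    }
  }
  out <- matrix(NA_real_, n_steps, n_chains)
  for (i in seq_len(n_steps)) {
    z <- step(z)
    if (any(!is.finite(z))) {
      stop("numerical-stability error: non-finite state at step ", i,
           "; use a smaller dt", call. = FALSE)
    }
    out[i, ] <- z
  }
  out
}

#' Specification of a cusp-process observation set
#'
#' Canonical coefficients of the three linear maps (state, asymmetry,
#' bifurcation) plus the covariate series that drive the per-year control
#' parameters.
#'
#' @param omega0,omega1 state map: z = omega0 + omega1 * state (omega1 > 0).
#' @param a0,a1 asymmetry map: alpha_t = a0 + a1 * asym_cov_t.
#' @param b0,b1 bifurcation map: beta_t = b0 + b1 * bifur_cov_t.
#' @param asym_cov,bifur_cov covariate series (equal length, the sample size).
#' @param sigma_z diffusion scale; the default sqrt(2) makes the SDE's
#'   stationary law the canonical density.
#' @param dt,burn_in SDE discretisation, used only when simulating via the
#'   SDE route.
#' @param seed integer seed.
#' @return a `cusp_sim_spec` list.
#' @export
cusp_sim_spec <- function(omega0, omega1, a0, a1, b0, b1,
                          asym_cov, bifur_cov, sigma_z = sqrt(2),
                          dt = 1e-3, burn_in = 1e5, seed = 1L) {
  stopifnot(length(asym_cov) == length(bifur_cov), length(asym_cov) >= 1,
            sigma_z > 0, dt > 0, omega1 != 0)
  structure(list(omega0 = omega0, omega1 = omega1, a0 = a0, a1 = a1,
                 b0 = b0, b1 = b1, asym_cov = asym_cov,
                 bifur_cov = bifur_cov, sigma_z = sigma_z, dt = dt,
                 burn_in = burn_in, seed = as.integer(seed)),
            class = "cusp_sim_spec")
}

#' Simulate observations from the cusp measurement model
#'
#' For each observation t the control parameters are alpha_t = a0 + a1 *
#' asym_cov_t and beta_t = b0 + b1 * bifur_cov_t; the canonical state z_t is
#' an independent draw from the stationary density at (alpha_t, beta_t), and
#' the observed state is the inverse of the state map, (z_t - omega0) /
#' omega1.
#'
#' @param spec a [cusp_sim_spec()].
#' @return data.frame with columns `state`, `asym`, `bifur`, `z`, `alpha`,
#'   `beta`, `delta`, `class` (true per-year classification).
#' @export
simulate_cusp_series <- function(spec) {
  stopifnot(inherits(spec, "cusp_sim_spec"))
  set.seed(spec$seed)
  n <- length(spec$asym_cov)
  alpha <- spec$a0 + spec$a1 * spec$asym_cov
  beta <- spec$b0 + spec$b1 * spec$bifur_cov
  z <- vapply(seq_len(n),
              function(t) sample_cusp_stationary(alpha[t], beta[t], 1L),
              numeric(1))
  delta <- cardan_discriminant(alpha, beta)
  data.frame(state = (z - spec$omega0) / spec$omega1,
             asym = spec$asym_cov, bifur = spec$bifur_cov,
             z = z, alpha = alpha, beta = beta, delta = delta,
             class = ifelse(delta < 0, "bistable", "stable"),
             stringsAsFactors = FALSE)
}

#' Packaged 49-year tipping fixture
#'
#' A synthetic stock table built from a cusp process whose control path
#' starts inside the bifurcation (bistable) region and ends well outside it
#' at a low state: SST trends upward, scaled pressure F/R rises, and the
#' canonical state tracks the stable equilibrium nearest its previous value
#' (the delay convention), so the series drops abruptly when its upper basin
#' folds away and then stays locked in the low branch.  Fishing mortality F
#' carries four regimes with F mostly above 1.0 in the second; recruitment
#' follows as F divided by the scaled-pressure path.  The end-to-end demo
#' input for the whole pipeline.
#'
#' @param seed integer seed (default 7).
#' @return a validated `stock_series` of 49 years (1970--2018).
#' @export
make_tipping_fixture <- function(seed = 7L) {
  set.seed(seed)
  years <- 1970:2018
  n <- length(years)
  tt <- (years - years[1]) / (n - 1)

  sst <- 7.2 + 2.0 * tt + stats::rnorm(n, 0, 0.12)
  # control maps: beta from SST (warming destabilises the fold),
  # alpha from F/R (pressure tilts the potential to the low branch)
  b0 <- 13.3; b1 <- -1.5
  a0 <- 0.8;  a1 <- -1.0
  fr <- 0.5 + 1.5 * tt + stats::rnorm(n, 0, 0.04)
  beta <- b0 + b1 * sst
  alpha <- a0 + a1 * fr

  z <- numeric(n)
  prev <- 1.5
  for (t in seq_len(n)) {
    eq <- cusp_equilibria(alpha[t], beta[t])
    stable <- eq$z[eq$stability == "stable"]
    prev <- stable[which.min(abs(stable - prev))]
    z[t] <- prev + stats::rnorm(1, 0, 0.12)
  }
  ssb <- 20000 + 7000 * z

  f_regime <- findInterval(years, c(1970, 1986, 1994, 2008))
  f <- c(0.9, 1.3, 1.05, 0.8)[f_regime] + stats::rnorm(n, 0, 0.05)
  recruitment <- f / fr

  stock_series(years, ssb, recruitment, f, sst)
}
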