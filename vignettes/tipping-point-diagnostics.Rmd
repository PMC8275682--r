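---
title: "Tipping-point diagnostics for exploited fish stocks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tipping-point diagnostics for exploited fish stocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codtip)
```

# The scientific question

A collapsed fish stock that fails to recover after fishing pressure is
relaxed is the classic signature of a regime shift with hysteresis: the
system has crossed a tipping point into an alternative state that ordinary
management levers no longer reach.  `codtip` implements a three-stage
evidence chain for diagnosing such dynamics from standard annual
stock-assessment output — spawning stock biomass (SSB, tonnes), recruitment
at age 1 (R), fishing mortality (F, per year) — plus a sea surface
temperature series (SST, °C):

1. **Abrupt changes**: multiple changepoints in the mean of single series
   (SSB, R, and the productivity index R/SSB).
2. **Non-stationary functioning**: structural breaks in six bivariate
   linear relationships among the variables.
3. **Alternative stable states**: a stochastic cusp catastrophe model that
   classifies each year as bistable (inside the cusp area, where two stable
   states coexist and abrupt jumps and hysteresis are possible) or stable
   (a single equilibrium, which late in a collapse means a *locked-in* low
   state).

Two derived indices carry much of the signal: `productivity = R/SSB`
(recruits per unit spawning biomass) and `scaled_pressure = F/R` (fishing
mortality per unit of incoming year-class strength — exploitation pressure
relative to what the stock can currently produce).

# Stage 1: mean changepoints

For a series $x_{1:n}$ the segment cost is the Gaussian twice-negative
log-likelihood under a segment-specific mean and a **common** variance,

$$C(x_{i:j}) = \sum_{t=i}^{j}\frac{(x_t-\bar x_{i:j})^2}{\hat\sigma^2},
\qquad
\hat\sigma^2 = \tfrac12\,\mathrm{Var}(\Delta x),$$

and the optimizer minimizes $\sum_{\text{seg}} C + m\,p$ over all
segmentations with $m$ changepoints.  Choices that matter:

* **Scale estimate.** Half the variance of first differences is used
  because differences are unaffected by piecewise-constant mean shifts
  except at the few shift points, so the estimate is robust to the very
  regimes being detected.  Holding the variance common across segments
  prevents variance changes from masquerading as mean changes.
* **Penalty.** The AIC rule, $p = 2k$ with $k = 2$ parameters per
  changepoint (one mean, one position), giving the default $p = 4$.  $k$
  is exposed in `aic_penalty()`.
* **Minimum segment length.** Default 10 years — a floor on what counts as
  a regime in an annual stock series, and the value used throughout the
  packaged analyses.
* **Exactness.** The dynamic program is PELT with the standard $K=0$
  pruning inequality for this subadditive quadratic cost.  With a minimum
  segment length, a pruned candidate is retired only once its dominating
  candidate is itself admissible; correctness is certified against
  `exhaustive_segmentation()`, an independent enumeration oracle, on
  hundreds of random instances rather than assumed.
* **Conventions.** A changepoint is the calendar year of the last
  observation of the closing segment; ties in cost are broken toward fewer
  changepoints, then earliest positions.

# Stage 2: structural breaks in relationships

For a response/covariate pair observed in time order, `dp_breakpoints()`
finds, for every $m$ up to `max_breaks`, the partition of the series into
$m+1$ contiguous regimes minimizing the total OLS residual sum of squares,
with both intercept and slope free to shift at each break.  The triangular
matrix of segment RSS values is computed once from prefix sums and shared
across all $m$.  The break count is chosen by

$$\mathrm{BIC}(m) = n\log(\mathrm{RSS}_m/n) + \bigl(2(m+1)+m\bigr)\log n,$$

ties toward smaller $m$.  Two deliberate simplifications: the minimum
regime size defaults to $\lceil 0.15\,n\rceil$ observations (configurable;
it prevents two-point regimes), and no sup-F significance test is run —
the evidence summary is $\Delta\mathrm{BIC}$ between the no-break model
and the chosen one.  Breaks are positions in *time* order; sorting by the
covariate would change the answer, and the time-order convention is the
standard one for structural-change analysis.

The six default relationships are SSB~F, SSB~F/R, R~SSB, R~SST, R/SSB~SSB
and R/SSB~SST.

# Stage 3: the stochastic cusp model

The canonical cusp potential is

$$V(z;\alpha,\beta) = \tfrac14 z^4 - \tfrac12\beta z^2 - \alpha z,$$

whose critical points solve $\alpha + \beta z - z^3 = 0$.  Cardan's
discriminant $\delta = 27\alpha^2 - 4\beta^3$ determines the root count:
one real equilibrium for $\delta > 0$ (stable), three for $\delta < 0$
(bistable; two minima separated by a maximum).  The set
$\alpha = \pm\sqrt{4\beta^3/27}$, $\beta \ge 0$, bounds the cusp area.
Adding white noise gives
$dz = (-z^3+\beta z+\alpha)\,dt + \sigma_z\,dW$ with stationary density
$f(z)\propto\exp\!\bigl(2(\alpha z + \tfrac12\beta z^2 - \tfrac14
z^4)/\sigma_z^2\bigr)$; in the canonical scaling $\sigma_z^2 = 2$ the
exponent is simply $\alpha z + \beta z^2/2 - z^4/4$, and the fitting
module works in that scaling (the simulator exposes $\sigma_z$
explicitly).

The three canonical variables are linear in observables:

$$z_t = \omega_0 + \omega_1\,\mathrm{SSB}_t,\qquad
\alpha_t = \alpha_0 + \alpha_1\,(F/R)_t,\qquad
\beta_t = \beta_0 + \beta_1\,\mathrm{SST}_t,$$

and `fit_cusp()` maximizes $\sum_t \log f(z_t;\alpha_t,\beta_t)$ over the
six coefficients.  Numerical and identification choices:

* **Jacobian.** The likelihood is the density of the *observed* state, so
  the affine state map contributes $n\log|\omega_1|$; omitting it makes
  the likelihood unbounded as $\omega_1 \to 0$.
* **Sign convention.** The model is invariant under jointly flipping the
  state and asymmetry maps ($z\to-z$, $\alpha\to-\alpha$); $\omega_1 > 0$
  is imposed, without loss of generality, via the optimizer bounds.
* **Standardization.** State and covariates are standardized internally
  (the canonical coefficients are affine-equivariant, so classifications
  and the reported raw-scale coefficients are unchanged); box constraints
  $[-8, 8]$ on the standardized coefficients keep the control parameters
  in a numerically safe range.
* **Normalizing constants.** Inside the optimizer the per-year constants
  $C(\alpha_t,\beta_t)$ and the moments needed for the analytic gradient
  are evaluated by a shared trapezoid grid (501 points spanning all
  equilibria plus quartic tails, log-sum-exp guarded); the integrand
  decays like $e^{-z^4/4}$, so the truncation error is far below the
  optimizer's tolerance.  The user-facing `cusp_stationary_density()`
  uses adaptive quadrature (`integrate`, rel. tol. 1e-10) and integrates
  to 1 within 1e-8.
* **Multi-start.** Eight deterministic starts — the four sign patterns of
  $(\alpha_1,\beta_1)$ crossed with a monostable ($\beta_0=0$) and a
  bistable ($\beta_0=1.5$) intercept — guard against the multimodal
  likelihood.  The reported optimum is verified in the tests to beat
  every start.
* **Prediction.** `nearest_mode` (default) maps each year to the density
  mode nearest the observed canonical state — the *delay* convention,
  which is the one that expresses hysteresis; `expected_value` gives the
  stationary mean as a sensitivity check.  Cobb's pseudo-$R^2$ is
  $1-\mathrm{Var}(z-\hat z)/\mathrm{Var}(z)$ on canonical states.

## Validation protocol

`validate_cusp()` reports: (i) a Wald test of $\omega_1$ at 5% (from the
numerical Hessian at the optimum); (ii) a bimodality check — a dip test on
the canonical states of bistable-classified years, requiring at least 10
such years to be assessable; (iii) the percentage of observations inside
the cusp area; (iv) pseudo-$R^2$ plus an AIC comparison against a linear
model ($\mathrm{state}\sim\mathrm{asym}+\mathrm{bifur}$) and a logistic
curve ($L/(1+e^{-(c_0+c_1 a+c_2 b)})$ with Gaussian error, all parameters
counted).  The verdict is `valid` iff (i) passes, the cusp AIC is lowest
and the cusp area is non-empty.  All three AICs are expressed for the raw
state variable (the cusp log-likelihood is shifted by the affine Jacobian
of the internal standardization) so they refer to the same random
variable; comparing a stationary-density likelihood with least-squares
likelihoods is nevertheless approximate, and the report prints that
caveat.

The dip statistic is computed by bisection on the sup-distance between the
empirical CDF and the class of unimodal CDFs (convex below the mode,
concave above, atom permitted at the mode), testing band feasibility with
monotone-chain hulls at every modal split.  It reproduces the closed-form
values on canonical cases (equally spaced points: $1/(2n)$; balanced
two-point clusters: $1/4$), and its p-value is calibrated by Monte Carlo
against uniform samples of the same size — the standard null — with the
same statistic on both sides, so the test's level does not depend on any
residual approximation in the statistic.

# The synthetic-data module

Because assessment databases cannot be redistributed, every stage is
exercised on generated data whose structure matches what the analysis
assumes:

* `simulate_regime_series()` draws piecewise-constant-mean Gaussian series
  (four regimes over 49 years in the packaged specs, regime shifts of
  about 4 within-regime standard deviations, segments of at least 10
  years) plus a linear-trend SST.
* `sample_cusp_stationary()` draws i.i.d. canonical states by inverse-CDF
  on a $2^{14}$-point grid (rejection sampling was rejected: its cost is
  unbounded for extreme $\beta$); `simulate_cusp_sde()` is a fixed-step
  Euler–Maruyama integrator (default $dt=10^{-3}$) whose long-run law is
  checked against the quadrature density in the tests.
* `make_tipping_fixture()` packages a 49-year table (1970–2018) in which
  the control path starts inside the bifurcation region and ends outside
  it at a low state: SST warms by 2 °C, F/R triples, F exceeds 1.0
  throughout the second regime, and the canonical state follows the
  stable equilibrium nearest its previous value (the delay convention),
  so biomass drops abruptly when the upper basin folds away and stays
  locked on the low branch.

What the generators deliberately do **not** emulate: age structure,
stock-recruitment process models (Ricker/Beverton–Holt), autocorrelated
observation noise, and assessment-model error that is correlated across
SSB, R and F.  A passing test suite therefore certifies the *methods* —
exact optimization, correct densities, recoverable parameters under the
model's own assumptions — not the ecological correctness of any verdict on
real data.

# Problem sizes and runtime choices

The study-scale problems are small (a 49-year table; the full pipeline
runs in seconds), so the test suite certifies correctness at scales where
independent oracles are exact: segmenter-vs-enumeration on hundreds of
random instances of $n \le 40$, a $101\times101$ control-plane grid for
the discriminant, and coefficient recovery on 50 replicates of $n = 500$
cusp observations.  The recovery bounds (median absolute error per
coefficient: 0.06, 0.08, 0.12, 0.18, 0.40, 0.20 for $\omega_0, \omega_1,
\alpha_0, \alpha_1, \beta_0, \beta_1$; pooled classification accuracy at
least 90%) were fixed from an oracle run of the same harness before the
test was written, and are not tuned afterwards.

# Known limitations

* The likelihood treats years as independent draws from the stationary
  density; autocorrelation in the state series is ignored (shuffling rows
  leaves the fit unchanged), a recognised open problem for this model
  class.
* AIC comparability across the cusp and least-squares alternatives is
  approximate (see above).
* Breakpoint "significance" is summarized by $\Delta$BIC, not a formal
  sup-F test.
* The recruitment unit (thousands vs millions) is left to the user; both
  derived indices are scale-covariant and every downstream fit
  standardizes internally, so the choice cannot alter changepoints,
  breaks or state classifications.
* Reference levels (B_lim, MSY B_trigger, F_MSY, F_pa) annotate reports
  only; they enter no computation.
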