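#' @title Mean-changepoint detection by penalized exact dynamic programming
#'
#' @description
#' Detects multiple changepoints in the mean of a single annual series.  The
#' segment cost is the Gaussian twice-negative-log-likelihood of a
#' constant-mean segment under a common variance,
#' \deqn{C(x_{i:j}) = \sum_{t=i}^{j} (x_t - \bar x_{i:j})^2 / \hat\sigma^2,}
#' with \eqn{\hat\sigma^2} estimated as half the variance of the first
#' differences of the whole series.  First differences are unaffected by
#' mean shifts except at the shift points themselves, so the scale estimate
#' is robust to the very regime structure being detected; holding it common
#' across segments prevents variance changes from masquerading as mean
#' changes.  The optimizer minimizes \eqn{\sum_{seg} C(seg) + m \cdot
#' \mathrm{penalty}} over all segmentations with \eqn{m} changepoints and
#' segments of at least `min_segment_length` observations, using the PELT
#' (Pruned Exact Linear Time) dynamic program.  Pruning uses the standard
#' K = 0 inequality for this subadditive quadratic cost; with a minimum
#' segment length a pruned candidate is retired only once its dominating
#' candidate is itself admissible, which preserves exactness.
#'
#' A changepoint is reported as the calendar year of the LAST observation of
#' the closing segment.
#'
#' @name changepoint
NULL

# Common-variance scale: half the variance of first differences.
# Robust to piecewise-constant mean shifts (only the few difference terms
# straddling a shift are contaminated).
diff_var_scale <- function(series) {
  if (length(series) < 3L) return(1)
  s2 <- stats::var(diff(series)) / 2
  if (!is.finite(s2) || s2 < .Machine$double.eps) s2 <- 1
  s2
}

# Segment cost C(i..j) = sum of squared deviations from the segment mean,
# divided by the common variance scale. Returns closures over prefix sums.
segment_cost_fun <- function(series, scale = diff_var_scale(series)) {
  s1 <- c(0, cumsum(series))
  s2 <- c(0, cumsum(series^2))
  function(i, j) {
    n <- j - i + 1
    ((s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / n) / scale
  }
}

#' AIC changepoint penalty
#'
#' The penalty added per changepoint under an AIC rule: `2 * k` where `k`
#' is the number of additional parameters a changepoint introduces (one
#' segment mean plus one position under the default convention, so the
#' default penalty is 4).  The value does not depend on the series; the
#' `series` argument is accepted for interface symmetry with penalty rules
#' that do.
#'
#' @param series optional numeric series (ignored by this rule).
#' @param k parameters per changepoint (default 2).
#' @return the penalty, `2 * k`.
#' @export
aic_penalty <- function(series = NULL, k = 2) {
  2 * k
}

new_segmentation <- function(cps, series, years, penalty, min_segment_length,
                             scale) {
  n <- length(series)
  bounds <- c(0L, cps, n)
  segs <- lapply(seq_len(length(bounds) - 1L),
                 function(k) (bounds[k] + 1L):bounds[k + 1L])
  means <- vapply(segs, function(ix) mean(series[ix]), numeric(1))
  costf <- segment_cost_fun(series, scale)
  segcost <- vapply(seq_len(length(bounds) - 1L),
                    function(k) costf(bounds[k] + 1L, bounds[k + 1L]),
                    numeric(1))
  structure(list(
    changepoint_years = if (length(cps)) years[cps] else integer(0),
    changepoints = cps,
    m = length(cps),
    segment_first_year = years[bounds[-length(bounds)] + 1L],
    segment_last_year = years[bounds[-1L]],
    segment_means = means,
    segment_costs = segcost,
    total_cost = sum(segcost) + length(cps) * penalty,
    penalty = penalty,
    min_segment_length = min_segment_length,
    n = n,
    years = years
  ), class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("Mean-changepoint segmentation:", x$m, "changepoint(s), penalty",
      format(x$penalty), "\n")
  if (x$m > 0) cat("  changepoint years (last year of closing segment):",
                   paste(x$changepoint_years, collapse = ", "), "\n")
  cat("  segment means:", paste(signif(x$segment_means, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Exact penalized mean-changepoint segmentation (PELT)
#'
#' @param series numeric vector, one observation per consecutive year.
#' @param penalty non-negative penalty per changepoint (default
#'   [aic_penalty()]).
#' @param min_segment_length minimum observations per segment (default 10,
#'   a reasonable minimum regime length for annual stock series).
#' @param years optional calendar-year labels (default `1:n` positions).
#' @return a `segmentation` with changepoint years, per-segment means, and
#'   the penalized total cost.
#' @examples
#' x <- c(rnorm(15, 0), rnorm(15, 8))
#' pelt_mean(x, penalty = 4, min_segment_length = 5)
#' @export
pelt_mean <- function(series, penalty = aic_penalty(),
                      min_segment_length = 10L, years = NULL) {
  n <- length(series)
  if (any(!is.finite(series))) {
    stop("changepoint validation error: non-finite values in series",
         call. = FALSE)
  }
  if (n < min_segment_length) {
    stop("no admissible segmentation: series length ", n,
         " is below the minimum segment length ", min_segment_length,
         call. = FALSE)
  }
  if (penalty < 0) stop("penalty must be non-negative", call. = FALSE)
  if (is.null(years)) years <- seq_len(n)
  stopifnot(length(years) == n)
  L <- as.integer(min_segment_length)
  scale <- diff_var_scale(series)
  cost <- segment_cost_fun(series, scale)
  tol <- 1e-9

  # F_[s+1] = optimal penalized cost of series[1..s]; F_[1] = -penalty so the
  # first segment is not charged.  cand holds candidate last-changepoint
  # positions s (0-based); pruned_at[s+1] records when s was dominated, and s
  # is retired only for t >= pruned_at + L so the dominating candidate is
  # itself admissible wherever s is dropped.
  F_ <- rep(Inf, n + 1L)
  M_ <- rep(0L, n + 1L)
  F_[1L] <- -penalty
  last_cp <- integer(n + 1L)
  pruned_at <- rep(Inf, n + 1L)
  cand <- 0L

  for (t in L:n) {
    usable <- cand[(t - cand) >= L & t < pruned_at[cand + 1L] + L]
    best_cost <- Inf; best_m <- NA_integer_; best_s <- NA_integer_
    cvals <- vapply(usable, function(s) cost(s + 1L, t), numeric(1))
    tot <- F_[usable + 1L] + cvals + penalty
    for (k in seq_along(usable)) {
      mk <- M_[usable[k] + 1L] + (usable[k] > 0L)
      if (tot[k] < best_cost - tol ||
          (tot[k] < best_cost + tol &&
           (mk < best_m || (mk == best_m && usable[k] < best_s)))) {
        best_cost <- tot[k]; best_m <- mk; best_s <- usable[k]
      }
    }
    F_[t + 1L] <- best_cost
    M_[t + 1L] <- best_m
    last_cp[t + 1L] <- best_s
    # K = 0 pruning
    drop <- F_[usable + 1L] + cvals > F_[t + 1L] + tol
    newly <- usable[drop & !is.finite(pruned_at[usable + 1L])]
    pruned_at[newly + 1L] <- t
    if (t <= n - L) cand <- c(cand, t)
    cand <- cand[(t + 1L) < pruned_at[cand + 1L] + L]
  }
  # F_[n+1] includes +penalty for the final (uncharged) segment; remove it.
  cps <- integer(0)
  s <- n
  while (s > 0L) {
    p <- last_cp[s + 1L]
    if (p > 0L) cps <- c(p, cps)
    s <- p
  }
  new_segmentation(cps, series, years, penalty, L, scale)
}

#' Exhaustive optimal segmentation (test oracle)
#'
#' Finds the global minimizer of the same penalized cost as [pelt_mean()] by
#' explicit enumeration of every admissible changepoint set with at most
#' `max_m` changepoints.  Intended as an independent correctness oracle for
#' small instances; refuses instances whose enumeration would be infeasible.
#'
#' @inheritParams pelt_mean
#' @param max_m maximum number of changepoints to enumerate (default
#'   `floor(n / min_segment_length) - 1`, i.e. unrestricted).
#' @return a `segmentation`.
#' @export
exhaustive_segmentation <- function(series, penalty = aic_penalty(),
                                    min_segment_length = 10L,
                                    max_m = NULL, years = NULL) {
  n <- length(series)
  if (any(!is.finite(series))) {
    stop("changepoint validation error: non-finite values in series",
         call. = FALSE)
  }
  L <- as.integer(min_segment_length)
  if (n < L) stop("no admissible segmentation", call. = FALSE)
  m_cap <- max(0L, n %/% L - 1L)
  if (is.null(max_m)) max_m <- m_cap
  max_m <- min(as.integer(max_m), m_cap)
  if (n > 60L && max_m > 3L) {
    stop("exhaustive enumeration refused: n > 60 and max_m > 3", call. = FALSE)
  }
  if (is.null(years)) years <- seq_len(n)
  scale <- diff_var_scale(series)
  cost <- segment_cost_fun(series, scale)
  # full triangular cost matrix for vectorized enumeration
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) C[i, i:n] <- cost(i, i:n)

  # admissible changepoint positions (0-based s means split after series[s])
  positions <- seq_len(n - 1L)
  positions <- positions[positions >= L & (n - positions) >= L]

  best <- list(cost = C[1L, n], cps = integer(0), m = 0L)
  tol <- 1e-9
  if (max_m >= 1L && length(positions) > 0L) {
    for (m in seq_len(max_m)) {
      if (length(positions) < m) break
      combos <- utils::combn(positions, m)
      if (m > 1L) {
        ok <- colSums(diff(combos) >= L) == m - 1L
        combos <- combos[, ok, drop = FALSE]
      }
      if (length(combos) == 0L || ncol(combos) == 0L) next
      starts <- rbind(1L, combos + 1L)
      ends <- rbind(combos, n)
      tc <- colSums(matrix(C[cbind(c(starts), c(ends))], nrow = m + 1L)) +
        m * penalty
      j <- which.min(tc)
      # re-scan ties for the deterministic order (rare outside constructions)
      ties <- which(tc < tc[j] + tol)
      if (length(ties) > 1L) {
        for (jj in ties) {
          if (first_lex_smaller(combos[, jj], combos[, j])) j <- jj
        }
      }
      if (tc[j] < best$cost - tol ||
          (tc[j] < best$cost + tol && m < best$m)) {
        best <- list(cost = tc[j], cps = combos[, j], m = m)
      }
    }
  }
  new_segmentation(best$cps, series, years, penalty, L, scale)
}

first_lex_smaller <- function(a, b) {
  if (length(b) == 0L) return(FALSE)
  k <- min(length(a), length(b))
  d <- a[seq_len(k)] - b[seq_len(k)]
  nz <- which(d != 0)
  if (length(nz) == 0L) return(length(a) < length(b))
  d[nz[1L]] < 0
}

#' Serialize a segmentation to JSON
#'
#' @param seg a `segmentation`.
#' @param series_name label recorded in the JSON.
#' @return a JSON string.
#' @export
segmentation_json <- function(seg, series_name = "series") {
  jsonlite::toJSON(list(series_name = series_name,
                        penalty = seg$penalty,
                        changepoint_years = seg$changepoint_years,
                        segment_means = seg$segment_means,
                        cost = seg$total_cost),
                   auto_unbox = TRUE, digits = NA)
}
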