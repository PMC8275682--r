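#' @title A Hartigan-type unimodality statistic and Monte-Carlo dip test
#'
#' @description
#' The dip of a sample is the smallest uniform (sup-norm) distance between
#' its empirical CDF and the class of unimodal distribution functions
#' (convex below the mode, concave above, with an atom permitted at the
#' mode).  It is computed here by bisection on the distance d: the
#' empirical CDF is bracketed by a band of half-width d, and a unimodal
#' function fits inside the band iff for some modal split the upper band
#' admits a convex minorant above the lower band on the left and the lower
#' band admits a concave majorant below the upper band on the right (both
#' checked with monotone-chain hulls); modal splits between and at data
#' points are both examined.  The dip of any n-point sample lies in
#' [1/(2n), 1/4] (0 for a single repeated value); large values indicate
#' multimodality.  The test calibrates the statistic by Monte Carlo against
#' uniform samples of the same size, the standard null for the dip.
#'
#' @name dip
NULL

# lower convex hull values of points (x, y) at every x; O(K)
lower_hull_values <- function(x, y) {
  K <- length(x)
  if (K <= 2L) return(y)
  hx <- numeric(K); hy <- numeric(K); m <- 0L
  for (i in seq_len(K)) {
    while (m >= 2L &&
           (hy[m] - hy[m - 1L]) * (x[i] - hx[m]) >=
           (y[i] - hy[m]) * (hx[m] - hx[m - 1L])) {
      m <- m - 1L
    }
    m <- m + 1L; hx[m] <- x[i]; hy[m] <- y[i]
  }
  stats::approx(hx[seq_len(m)], hy[seq_len(m)], xout = x,
                method = "linear", ties = "ordered")$y
}

convex_band_feasible <- function(x, l, h) {
  if (length(x) == 0L) return(TRUE)
  if (any(l > h + 1e-12)) return(FALSE)
  g <- lower_hull_values(x, h)
  all(g >= l - 1e-12)
}

concave_band_feasible <- function(x, l, h) {
  if (length(x) == 0L) return(TRUE)
  if (any(l > h + 1e-12)) return(FALSE)
  g <- -lower_hull_values(x, -l)   # least concave majorant of l
  all(g <= h + 1e-12)
}

unimodal_band_feasible <- function(v, cum, n, d) {
  K <- length(v)
  l <- pmax(cum / n - d, 0)
  h <- pmin(c(0, cum[-K]) / n + d, 1)
  # mode strictly between data points (or outside the range): split after k
  for (k in 0:K) {
    if (convex_band_feasible(v[seq_len(k)], l[seq_len(k)], h[seq_len(k)]) &&
        concave_band_feasible(v[seq.int(k + 1L, length.out = K - k)],
                              l[seq.int(k + 1L, length.out = K - k)],
                              h[seq.int(k + 1L, length.out = K - k)])) {
      return(TRUE)
    }
  }
  # mode at a data point with an atom: the point belongs to both pieces with
  # its band split at the jump
  cum0 <- c(0, cum[-K])
  for (j in seq_len(K)) {
    li <- seq_len(j); ri <- j:K
    ll <- l[li]; hh <- h[li]
    ll[j] <- max(cum0[j] / n - d, 0); hh[j] <- min(cum0[j] / n + d, 1)
    lr <- l[ri]; hr <- h[ri]
    lr[1L] <- max(cum[j] / n - d, 0); hr[1L] <- min(cum[j] / n + d, 1)
    if (convex_band_feasible(v[li], ll, hh) &&
        concave_band_feasible(v[ri], lr, hr)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Dip statistic
#'
#' @param x numeric sample (length >= 2 for a nontrivial value).
#' @param tol bisection tolerance on the statistic (default 1e-6).
#' @return the dip, a value in [0, 1/4].
#' @export
dip_statistic <- function(x, tol = 1e-6) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(0)
  v <- unique(x)
  cum <- cumsum(tabulate(match(x, v), nbins = length(v)))
  lo <- 0
  hi <- 0.251
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (unimodal_band_feasible(v, cum, n, mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Monte-Carlo dip test of unimodality
#'
#' @param x numeric sample.
#' @param B null resamples (default 200).
#' @param seed optional seed for the null resamples.
#' @return list `statistic`, `p_value`, `B`.
#' @export
dip_test <- function(x, B = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  stat <- dip_statistic(x)
  null <- vapply(seq_len(B), function(b) dip_statistic(stats::runif(n)),
                 numeric(1))
  list(statistic = stat,
       p_value = (1 + sum(null >= stat)) / (B + 1),
       B = B)
}
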