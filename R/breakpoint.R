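#' @title Multiple structural breaks in bivariate linear relationships
#'
#' @description
#' Locates breaks in the relationship between two annual series by finding,
#' for each candidate break count m, the partition of the time-ordered
#' observations into m + 1 contiguous regimes that minimizes the total
#' residual sum of squares (RSS) of regime-wise ordinary least squares fits
#' `response ~ covariate`.  Both intercept and slope are free to shift at
#' every break.  The optimal partitions are found by dynamic programming
#' over a triangular matrix of segment RSS values computed once from prefix
#' sums; the number of breaks is then chosen by BIC.  Breaks are positions
#' in TIME order (the observation index), not in covariate order, the
#' standard convention of structural-change analysis.
#'
#' @name breakpoint
NULL

# Triangular matrix of OLS residual sums of squares: rss_mat[i, j] is the
# RSS of response ~ covariate fitted to observations i..j (j >= i + 1).
# Closed form from prefix sums; a segment with (numerically) constant
# covariate falls back to the intercept-only RSS.
segment_rss_matrix <- function(response, covariate) {
  n <- length(response)
  sx <- c(0, cumsum(covariate)); sy <- c(0, cumsum(response))
  sxx <- c(0, cumsum(covariate^2)); syy <- c(0, cumsum(response^2))
  sxy <- c(0, cumsum(covariate * response))
  out <- matrix(NA_real_, n, n)
  scale_x <- max(1, max(covariate^2))
  for (i in seq_len(n)) {
    j <- i:n
    len <- j - i + 1
    cxx <- (sxx[j + 1] - sxx[i]) - (sx[j + 1] - sx[i])^2 / len
    cyy <- (syy[j + 1] - syy[i]) - (sy[j + 1] - sy[i])^2 / len
    cxy <- (sxy[j + 1] - sxy[i]) - (sx[j + 1] - sx[i]) * (sy[j + 1] - sy[i]) / len
    rss <- ifelse(cxx > 1e-12 * scale_x * len, cyy - cxy^2 / pmax(cxx, 1e-300), cyy)
    out[i, j] <- pmax(rss, 0)
  }
  out
}

#' Optimal break sets for each break count (RSS dynamic program)
#'
#' For every m = 0, ..., `max_breaks`, finds the set of m break positions
#' that globally minimizes the total regime-wise OLS residual sum of
#' squares, subject to every regime containing at least `min_segment`
#' observations.
#'
#' @param response numeric response series (time order).
#' @param covariate numeric covariate series, same length.
#' @param max_breaks largest break count to consider.
#' @param min_segment minimum observations per regime (>= 2; OLS needs two
#'   points).
#' @return list with one element per m (named `m0`, `m1`, ...), each a list
#'   `m`, `breaks` (0-based positions: break after observation `breaks[k]`),
#'   `rss`; plus attribute `rss_matrix` for reuse.
#' @export
dp_breakpoints <- function(response, covariate, max_breaks, min_segment) {
  n <- length(response)
  stopifnot(length(covariate) == n)
  if (min_segment < 2L) stop("min_segment must be >= 2 (OLS needs two points)",
                             call. = FALSE)
  if ((max_breaks + 1L) * min_segment > n) {
    stop("infeasible: ", max_breaks, " breaks with minimum segment ",
         min_segment, " exceed n = ", n, call. = FALSE)
  }
  L <- as.integer(min_segment)
  R <- segment_rss_matrix(response, covariate)

  # dp[k, j]: minimal RSS of observations 1..j split into k regimes
  kmax <- max_breaks + 1L
  dp <- matrix(Inf, kmax, n)
  back <- matrix(NA_integer_, kmax, n)
  dp[1L, L:n] <- R[1L, L:n]
  if (kmax > 1L) {
    for (k in 2L:kmax) {
      for (j in (k * L):n) {
        s <- ((k - 1L) * L):(j - L)   # last obs of regime k-1
        vals <- dp[k - 1L, s] + R[s + 1L, j]
        b <- which.min(vals)          # earliest on ties
        dp[k, j] <- vals[b]
        back[k, j] <- s[b]
      }
    }
  }
  out <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    m <- k - 1L
    brk <- integer(0)
    if (m > 0L) {
      j <- n
      for (kk in k:2L) {
        brk <- c(back[kk, j], brk)
        j <- back[kk, j]
      }
    }
    out[[k]] <- list(m = m, breaks = brk, rss = dp[k, n])
  }
  names(out) <- paste0("m", seq_len(kmax) - 1L)
  attr(out, "rss_matrix") <- R
  attr(out, "n") <- n
  attr(out, "min_segment") <- L
  out
}

#' Exhaustive break enumeration (test oracle)
#'
#' Enumerates every admissible break set with up to `max_breaks` breaks and
#' returns the RSS-minimal one per m.  Independent of the dynamic program;
#' used to certify it on small instances.
#'
#' @inheritParams dp_breakpoints
#' @return same structure as [dp_breakpoints()].
#' @export
exhaustive_breakpoints <- function(response, covariate, max_breaks,
                                   min_segment) {
  n <- length(response)
  if (n > 60L || max_breaks > 3L) {
    stop("exhaustive enumeration refused: n > 60 or max_breaks > 3",
         call. = FALSE)
  }
  L <- as.integer(min_segment)
  R <- segment_rss_matrix(response, covariate)
  positions <- seq_len(n - 1L)
  positions <- positions[positions >= L & (n - positions) >= L]
  out <- list(list(m = 0L, breaks = integer(0), rss = R[1L, n]))
  for (m in seq_len(max_breaks)) {
    if ((m + 1L) * L > n) break
    combos <- utils::combn(positions, m)
    if (m > 1L) {
      ok <- apply(combos, 2L, function(cp) all(diff(cp) >= L))
      combos <- combos[, ok, drop = FALSE]
    }
    best <- list(m = m, breaks = integer(0), rss = Inf)
    if (ncol(combos) > 0L) {
      for (jcol in seq_len(ncol(combos))) {
        cp <- combos[, jcol]
        bounds <- c(0L, cp, n)
        tot <- sum(R[cbind(bounds[-length(bounds)] + 1L, bounds[-1L])])
        if (tot < best$rss) best <- list(m = m, breaks = cp, rss = tot)
      }
    }
    out[[m + 1L]] <- best
  }
  names(out) <- paste0("m", seq_along(out) - 1L)
  attr(out, "rss_matrix") <- R
  attr(out, "n") <- n
  attr(out, "min_segment") <- L
  out
}

#' Choose the number of breaks by BIC
#'
#' BIC(m) = n log(RSS_m / n) + (p (m+1) + m) log n with p = 2 coefficients
#' per regime; ties resolved toward smaller m.
#'
#' @param per_m_results output of [dp_breakpoints()].
#' @param n sample size.
#' @return list `m` (chosen break count), `bic` (per-m values, named by m).
#' @export
select_num_breaks <- function(per_m_results, n) {
  stopifnot(length(per_m_results) > 0L)
  ms <- vapply(per_m_results, `[[`, integer(1), "m")
  rss <- vapply(per_m_results, `[[`, numeric(1), "rss")
  p <- 2
  bic <- n * log(pmax(rss, 1e-300) / n) + (p * (ms + 1) + ms) * log(n)
  bic[rss <= 0] <- -Inf
  ord <- order(ms)
  best <- ord[which.min(bic[ord])]   # first minimum in ascending m = tie to smaller m
  list(m = unname(ms[best]), bic = stats::setNames(unname(bic), paste0("m", ms)))
}

#' Fit one response~covariate relationship with structural breaks
#'
#' Runs the RSS dynamic program, selects m by BIC, and fits regime-wise
#' OLS coefficients.
#'
#' @param table a `stock_series`.
#' @param response,covariate column names in `table`.
#' @param max_breaks maximum break count.
#' @param min_segment minimum regime size in observations.
#' @return a `breakpoint_fit`: break years (last year of each regime before
#'   a break), per-regime coefficients, RSS, BIC table and the
#'   delta-BIC(m=0 vs chosen) evidence summary.
#' @export
fit_breakpoint <- function(table, response, covariate,
                           max_breaks = NULL, min_segment = NULL) {
  for (v in c(response, covariate)) {
    if (!v %in% names(table)) {
      stop("config error: unknown variable name '", v, "'", call. = FALSE)
    }
  }
  y <- table[[response]]; x <- table[[covariate]]
  n <- length(y)
  if (is.null(min_segment)) min_segment <- as.integer(ceiling(0.15 * n))
  min_segment <- max(2L, as.integer(min_segment))
  feasible_max <- n %/% min_segment - 1L
  if (is.null(max_breaks)) max_breaks <- 5L
  max_breaks <- max(0L, min(as.integer(max_breaks), feasible_max))
  per_m <- dp_breakpoints(y, x, max_breaks, min_segment)
  sel <- select_num_breaks(per_m, n)
  chosen <- per_m[[paste0("m", sel$m)]]
  bounds <- c(0L, chosen$breaks, n)
  regimes <- lapply(seq_len(length(bounds) - 1L), function(k) {
    ix <- (bounds[k] + 1L):bounds[k + 1L]
    xr <- x[ix]; yr <- y[ix]
    if (stats::sd(xr) < 1e-10 * max(1, mean(abs(xr)))) {
      warning("regime ", k, " of ", response, "~", covariate,
              " has constant covariate; fitted intercept-only", call. = FALSE)
      coefs <- c(intercept = mean(yr), slope = 0)
      rss <- sum((yr - mean(yr))^2)
    } else {
      fit <- stats::lm.fit(cbind(1, xr), yr)
      coefs <- c(intercept = fit$coefficients[1], slope = fit$coefficients[2])
      rss <- sum(fit$residuals^2)
    }
    list(first_year = table$year[ix[1L]],
         last_year = table$year[ix[length(ix)]],
         intercept = unname(coefs[1]), slope = unname(coefs[2]), rss = rss)
  })
  structure(list(
    response_name = response, covariate_name = covariate,
    break_years = if (sel$m > 0L) table$year[chosen$breaks] else integer(0),
    m = sel$m,
    regimes = regimes,
    rss = chosen$rss,
    ic_table = sel$bic,
    delta_bic_vs_m0 = unname(sel$bic["m0"] - min(sel$bic)),
    min_segment = min_segment,
    n = n
  ), class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Structural-break fit ", x$response_name, " ~ ", x$covariate_name,
      ": ", x$m, " break(s)", sep = "")
  if (x$m > 0) cat(" after year(s) ", paste(x$break_years, collapse = ", "),
                   sep = "")
  cat("\n  total RSS ", signif(x$rss, 5), "; delta-BIC vs no-break model ",
      signif(x$delta_bic_vs_m0, 4), "\n", sep = "")
  invisible(x)
}

#' Fit all configured bivariate relationships
#'
#' One [fit_breakpoint()] per configured `(response, covariate)` pair; the
#' default six pairs are SSB~F, SSB~F/R, R~SSB, R~SST, R/SSB~SSB and
#' R/SSB~SST.
#'
#' @param table a `stock_series`.
#' @param config an [analysis_config()].
#' @return named list of `breakpoint_fit` objects
#'   (`response~covariate` names).
#' @export
fit_relationships <- function(table, config = analysis_config()) {
  n <- nrow(table)
  min_segment <- max(2L, as.integer(ceiling(config$min_break_fraction * n)))
  fits <- lapply(config$relationships, function(pair) {
    fit_breakpoint(table, pair[[1]], pair[[2]],
                   max_breaks = config$max_breaks, min_segment = min_segment)
  })
  names(fits) <- vapply(config$relationships,
                        function(p) paste0(p[[1]], "~", p[[2]]), character(1))
  fits
}

#' Serialize a breakpoint fit to JSON
#' @param fit a `breakpoint_fit`.
#' @return JSON string.
#' @export
breakpoint_json <- function(fit) {
  jsonlite::toJSON(list(
    response = fit$response_name, covariate = fit$covariate_name,
    break_years = fit$break_years,
    regimes = lapply(fit$regimes, function(r) r[c("first_year", "last_year",
                                                  "intercept", "slope", "rss")]),
    bic_by_m = as.list(fit$ic_table)
  ), auto_unbox = TRUE, digits = NA)
}
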