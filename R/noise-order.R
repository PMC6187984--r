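#' Null-conform residual series of a PARCS fit
#'
#' Removes the fitted step structure from the series to obtain an estimate
#' of the no-change null: the fitted piecewise-linear model is subtracted
#' from the CUSUM curve, and the CUSUM transformation is inverted by first
#' differences (with `y_0 = 0`) plus the original column means,
#' `x0_t = y0_t - y0_{t-1} + mean(x)`.
#'
#' @param object a fitted [parcs()] model.
#' @return A `T x N` matrix carrying attribute `"source_knots"`.
#' @export
h0_series <- function(object) {
  stopifnot(inherits(object, "parcs"))
  y0 <- object$y - object$fitted
  x0 <- apply(rbind(0, y0), 2L, diff)
  x0 <- matrix(x0, object$T_len, object$N)
  x0 <- sweep(x0, 2L, object$x_mean, "+")
  attr(x0, "source_knots") <- object$knots
  x0
}

#' Sample autocorrelation at a given lag
#'
#' Biased (denominator `T`) sample autocorrelation with overall-mean
#' centering: numerator summed over the `T - tau` overlapping pairs,
#' denominator the full sum of squared deviations.  This is the estimator
#' whose null distribution at lag `tau` is approximately
#' `N(-1/(T - tau), 1/(T - tau))`.
#'
#' @param x univariate numeric series.
#' @param tau nonnegative integer lag, `tau < T`.
#' @return Correlation in `[-1, 1]`.
#' @export
autocorr <- function(x, tau) {
  x <- as.numeric(x)
  T_len <- length(x)
  tau <- as.integer(tau)
  if (tau < 0L || tau >= T_len) stop("lag must satisfy 0 <= tau < T")
  d <- x - mean(x)
  den <- sum(d^2)
  if (den <= 0) stop("zero-variance series: autocorrelation undefined")
  if (tau == 0L) return(1)
  sum(d[seq_len(T_len - tau)] * d[(tau + 1L):T_len]) / den
}

#' Estimate the moving-average order of a residual series
#'
#' The autocorrelation of an MA(q) process cuts off after lag `q`.  Scanning
#' lags `tau = 1, 2, ...`, each sample autocorrelation is tested against the
#' two-sided `(1 - alpha)` interval of its asymptotic null distribution
#' `N(-1/(T - tau), 1/(T - tau))`; the scan stops at the first lag that
#' fails to reject, returning `tau - 1`.  If every lag up to `Q` rejects,
#' `Q` is returned.  For multivariate input the order is estimated per
#' column and the maximum is used, a conservative choice that preserves
#' dependence in all columns when the result sets the bootstrap block size
#' (`k = q + 1`).
#'
#' @param x0 numeric vector or matrix, typically the output of
#'   [h0_series()].
#' @param Q upper bound on the order; the default 9 caps the downstream
#'   block size at 10.
#' @param alpha significance level of the per-lag test.
#' @return Integer order `q` in `0:Q`.
#' @export
estimate_ma_order <- function(x0, Q = 9L, alpha = 0.05) {
  x0 <- as_series_matrix(x0)
  Q <- as.integer(Q)
  T_len <- nrow(x0)
  if (Q < 1L) stop("Q must be at least 1")
  if (Q >= T_len) stop("Q must be smaller than the series length")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  one_col <- function(v) {
    q <- Q
    for (tau in seq_len(Q)) {
      m <- -1 / (T_len - tau)
      s <- sqrt(1 / (T_len - tau))
      lo <- stats::qnorm(alpha / 2, mean = m, sd = s)
      hi <- stats::qnorm(1 - alpha / 2, mean = m, sd = s)
      a <- autocorr(v, tau)
      if (a >= lo && a <= hi) {
        q <- tau - 1L
        break
      }
    }
    q
  }
  max(vapply(seq_len(ncol(x0)), function(n) one_col(x0[, n]), 0L))
}
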