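#' Invert a PARCS fit to step-model estimates
#'
#' Translates the fitted piecewise-linear CUSUM model back to the scale of
#' the observed series.  The slope change of the fitted curve at knot `c_m`
#' (the bend coefficient, `beta+_mn + beta-_mn` in the paired-spline
#' parameterization) estimates the step size; the reconstructed
#' piecewise-constant mean is the first difference of the fitted curve plus
#' the original series mean, and the baseline is its value on the first
#' segment.
#'
#' @param object a fitted [parcs()] model.
#' @return A list with `knots` (ranked locations), `w` (M x N step
#'   estimates), `b` (length-N baseline estimates) and `mean` (T x N
#'   reconstructed piecewise-constant mean curve).
#' @export
step_estimates <- function(object) {
  stopifnot(inherits(object, "parcs"))
  w <- object$bend
  d <- apply(object$fitted, 2L, diff)
  d <- matrix(d, object$T_len - 1L, object$N)
  # the slope left of the first knot extends to t = 1 (the fitted value at
  # t = 1 itself carries the arbitrary integration constant)
  mu <- rbind(d[1L, , drop = FALSE], d)
  mu <- sweep(mu, 2L, object$x_mean, "+")
  if (nrow(w)) rownames(w) <- paste0("c", object$knots)
  list(knots = object$knots, w = w, b = mu[1L, ], mean = mu)
}

#' @export
print.parcs <- function(x, digits = 4L, ...) {
  cat(sprintf("PARCS_%d model (T = %d, N = %d)\n", length(x$knots),
              x$T_len, x$N))
  if (length(x$knots)) {
    st <- step_estimates(x)
    cat("Ranked change point candidates and step estimates:\n")
    tab <- data.frame(rank = seq_along(x$knots), location = x$knots,
                      round(st$w, digits))
    names(tab)[-(1:2)] <- if (x$N == 1L) "w" else paste0("w.", seq_len(x$N))
    print(tab, row.names = FALSE)
  } else cat("Intercept-only model (no change points)\n")
  cat(sprintf("Residual MSE of the CUSUM fit: %.*g\n", digits, x$mse))
  invisible(x)
}

#' @export
summary.parcs <- function(object, ...) {
  st <- step_estimates(object)
  out <- list(knots = object$knots, w = st$w, b = st$b, mse = object$mse,
              T_len = object$T_len, N = object$N, M = object$M, L = object$L,
              forward_mse = object$forward_mse, degenerate = object$degenerate)
  class(out) <- "summary.parcs"
  out
}

#' @export
print.summary.parcs <- function(x, digits = 4L, ...) {
  cat(sprintf("PARCS_%d model of a T = %d, N = %d series (forward bound L = %d)\n",
              length(x$knots), x$T_len, x$N, x$L))
  if (x$degenerate) cat("NOTE: input series is constant; fit is degenerate\n")
  if (length(x$knots)) {
    cat("Ranked candidates (location, per-series step estimate):\n")
    for (m in seq_along(x$knots))
      cat(sprintf("  %d: t = %d, w = %s\n", m, x$knots[m],
                  paste(signif(x$w[m, ], digits), collapse = ", ")))
    cat("Baseline estimates:", paste(signif(x$b, digits), collapse = ", "), "\n")
  }
  if (!is.null(x$forward_mse))
    cat("Forward-stage MSE path:",
        paste(signif(x$forward_mse, 3L), collapse = " -> "), "\n")
  cat(sprintf("Residual MSE: %.*g\n", digits, x$mse))
  invisible(x)
}

#' Extract PARCS coefficients
#'
#' @param object a fitted [parcs()] model.
#' @param type `"splines"` returns the regression coefficients of the
#'   identified piecewise-linear basis (intercept, slope, one bend
#'   coefficient per knot); `"steps"` returns the implied step sizes (the
#'   bend coefficients) per knot and series.
#' @param ... unused.
#' @export
coef.parcs <- function(object, type = c("splines", "steps"), ...) {
  type <- match.arg(type)
  if (type == "splines") object$coefficients else step_estimates(object)$w
}

#' @export
fitted.parcs <- function(object, ...) object$fitted

#' Residuals of a PARCS fit
#'
#' @param object a fitted [parcs()] model.
#' @param scale `"cusum"` gives residuals of the piecewise-linear fit to the
#'   CUSUM curve; `"series"` gives residuals of the observed series around
#'   the reconstructed piecewise-constant mean (the basis of the
#'   null-conform series used for bootstrapping).
#' @param ... unused.
#' @export
residuals.parcs <- function(object, scale = c("cusum", "series"), ...) {
  scale <- match.arg(scale)
  if (scale == "cusum") object$residuals
  else object$x - step_estimates(object)$mean
}

#' Predict from a PARCS fit
#'
#' @param object a fitted [parcs()] model.
#' @param type `"mean"` returns the reconstructed piecewise-constant mean of
#'   the series; `"cusum"` the fitted piecewise-linear CUSUM curve.
#' @param ... unused.
#' @export
predict.parcs <- function(object, type = c("mean", "cusum"), ...) {
  type <- match.arg(type)
  if (type == "cusum") object$fitted else step_estimates(object)$mean
}

#' Simulate series from a fitted PARCS model
#'
#' Parametric-ish simulation: the reconstructed piecewise-constant mean plus
#' block-permuted model residuals (on the series scale), preserving
#' short-range temporal dependence up to the chosen block size.
#'
#' @param object a fitted [parcs()] model.
#' @param nsim number of simulated series.
#' @param seed optional integer seed.
#' @param k block size for residual permutation (1 = i.i.d. resampling of
#'   residual time points).
#' @param ... unused.
#' @return A list of `nsim` simulated `T x N` matrices.
#' @export
simulate.parcs <- function(object, nsim = 1L, seed = NULL, k = 1L, ...) {
  if (!is.null(seed)) set.seed(seed)
  res <- residuals(object, scale = "series")
  mu <- step_estimates(object)$mean
  lapply(seq_len(nsim), function(i) mu + block_permute(res, k))
}

#' Plot a PARCS fit
#'
#' Two stacked panels: the observed series with the reconstructed
#' piecewise-constant mean, and the CUSUM curve with its piecewise-linear
#' fit; knot locations are marked by vertical dashed lines.
#'
#' @param x a fitted [parcs()] model.
#' @param series which covariate to display (default 1).
#' @param ... passed to [graphics::plot()].
#' @export
plot.parcs <- function(x, series = 1L, ...) {
  st <- step_estimates(x)
  t_idx <- seq_len(x$T_len)
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(t_idx, x$x[, series], type = "l", col = "grey40",
                 xlab = "time step", ylab = "x", main = "series and step mean",
                 ...)
  graphics::lines(t_idx, st$mean[, series], col = "red3", lwd = 2)
  graphics::abline(v = x$knots, lty = 2, col = "grey60")
  graphics::plot(t_idx, x$y[, series], type = "l", col = "grey40",
                 xlab = "time step", ylab = "y",
                 main = "CUSUM curve and PARCS fit")
  graphics::lines(t_idx, x$fitted[, series], col = "red3", lwd = 2)
  graphics::abline(v = x$knots, lty = 2, col = "grey60")
  invisible(x)
}
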