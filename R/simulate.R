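#' Specify a piecewise-constant step model
#'
#' Builds the generative specification of a piecewise-stationary time series:
#' per-covariate baseline levels, ordered change points, an M x N matrix of
#' step sizes, and a noise family.  Gaussian noise may be a finite
#' moving-average (MA) process \eqn{\epsilon_t + \sum_{\tau=1}^q \kappa_\tau
#' \epsilon_{t-\tau}} with i.i.d. innovations \eqn{\epsilon_t \sim N(0,
#' \sigma^2)}; alternatively the series are independent Poisson counts whose
#' rate follows the step profile.
#'
#' A change point at `c` takes effect from time step `c + 1` onwards
#' (discrete Heaviside convention: the indicator of `t - c` is 1 iff
#' `t > c`).  All detectors in this package report change points on the same
#' convention.
#'
#' @param T_len series length (number of time steps, at least 3).
#' @param N number of covariates (independent series sharing the change
#'   points).
#' @param baseline numeric vector of per-covariate baseline levels, recycled
#'   to length `N`.
#' @param cps strictly increasing integer change point locations in
#'   `2:(T_len - 1)`; may be empty.
#' @param weights step sizes: an `length(cps)` x `N` matrix, or a vector of
#'   length `length(cps)` when `N == 1` (or of length `N` when there is one
#'   change point).
#' @param noise `"gaussian_ma"` or `"poisson"`.
#' @param sigma innovation standard deviation for Gaussian noise; `0` gives
#'   the noiseless limit of the step model, which is convenient for exact
#'   checks.
#' @param kappas MA coefficients `kappa_1..kappa_q` (the lag-0 coefficient is
#'   implicitly 1 and must not be supplied); empty for white noise.
#' @param seed optional integer seed making simulation deterministic.
#'
#' @return An object of class `"step_model_spec"`.
#' @seealso [simulate_step_series()], [simulate_poisson_counts()]
#' @export
step_model_spec <- function(T_len, N = 1L, baseline = 0, cps = integer(),
                            weights = NULL, noise = c("gaussian_ma", "poisson"),
                            sigma = 1, kappas = numeric(), seed = NULL) {
  noise <- match.arg(noise)
  T_len <- as.integer(T_len)
  N <- as.integer(N)
  if (T_len < 3L) stop("series length must be at least 3")
  if (N < 1L) stop("need at least one covariate")
  cps <- as.integer(cps)
  M <- length(cps)
  if (M > 0L) {
    if (any(diff(cps) <= 0L)) stop("change points must be strictly increasing")
    if (cps[1L] <= 1L || cps[M] >= T_len)
      stop("change points must lie strictly inside 2:(T-1)")
  }
  baseline <- rep_len(as.numeric(baseline), N)
  if (is.null(weights)) {
    if (M > 0L) stop("weights required when change points are given")
    weights <- matrix(numeric(0), 0L, N)
  } else if (!is.matrix(weights)) {
    if (M == 1L) weights <- matrix(as.numeric(weights), 1L, N)
    else if (N == 1L) weights <- matrix(as.numeric(weights), M, 1L)
    else stop("weights must be an M x N matrix")
  }
  if (nrow(weights) != M || ncol(weights) != N)
    stop("weights must have one row per change point and one column per covariate")
  if (noise == "gaussian_ma") {
    if (sigma < 0) stop("sigma must be nonnegative")
    if (length(kappas) && any(!is.finite(kappas)))
      stop("MA coefficients must be finite")
  } else {
    if (length(kappas)) stop("Poisson counts take no MA coefficients")
    rates <- step_mean_profile(T_len, baseline, cps, weights)
    if (any(rates < 0)) stop("Poisson rates must be nonnegative in every segment")
  }
  structure(
    list(T_len = T_len, N = N, baseline = baseline, cps = cps,
         weights = weights, noise = noise, sigma = sigma,
         kappas = as.numeric(kappas),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "step_model_spec")
}

#' @export
print.step_model_spec <- function(x, ...) {
  cat(sprintf("Step model: T = %d, N = %d, %d change point(s)\n",
              x$T_len, x$N, length(x$cps)))
  if (length(x$cps)) cat("  locations:", paste(x$cps, collapse = ", "), "\n")
  if (x$noise == "gaussian_ma") {
    q <- length(x$kappas)
    cat(sprintf("  noise: Gaussian MA(%d), sigma = %g\n", q, x$sigma))
  } else cat("  noise: Poisson counts\n")
  invisible(x)
}

## deterministic mean/rate profile of the step model, T x N
step_mean_profile <- function(T_len, baseline, cps, weights) {
  mu <- matrix(rep(baseline, each = T_len), T_len, length(baseline))
  t_idx <- seq_len(T_len)
  for (m in seq_along(cps)) {
    on <- t_idx > cps[m]
    mu[on, ] <- mu[on, , drop = FALSE] +
      rep(weights[m, ], each = sum(on))
  }
  mu
}

#' Simulate a step-mean series with (moving-average) Gaussian noise
#'
#' Draws a `T x N` matrix from the piecewise-constant step model: each column
#' follows its baseline plus the cumulative step weights, with additive MA(q)
#' Gaussian noise.  `q` extra pre-sample innovations are drawn so that the
#' noise process is stationary from the first time step onwards.
#'
#' @param spec a [step_model_spec()] with `noise = "gaussian_ma"`.
#' @return A numeric `T x N` matrix.
#' @examples
#' spec <- step_model_spec(100, cps = 20, weights = 1, sigma = 0.5, seed = 1)
#' x <- simulate_step_series(spec)
#' @export
simulate_step_series <- function(spec) {
  stopifnot(inherits(spec, "step_model_spec"))
  if (spec$noise != "gaussian_ma")
    stop("spec does not describe a Gaussian MA process")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  mu <- step_mean_profile(spec$T_len, spec$baseline, spec$cps, spec$weights)
  q <- length(spec$kappas)
  if (spec$sigma > 0) {
    eps <- matrix(stats::rnorm((spec$T_len + q) * spec$N, sd = spec$sigma),
                  spec$T_len + q, spec$N)
    if (q > 0) {
      noise <- stats::filter(eps, c(1, spec$kappas), method = "convolution",
                             sides = 1)
      noise <- matrix(noise[(q + 1):(spec$T_len + q), ], spec$T_len, spec$N)
    } else {
      noise <- eps
    }
    mu <- mu + noise
  }
  unname(mu)
}

#' Simulate piecewise-constant-rate Poisson counts
#'
#' Independent Poisson draws whose rate follows the step profile of the
#' specification, emulating spike-count series whose firing rate jumps at the
#' change points.
#'
#' @param spec a [step_model_spec()] with `noise = "poisson"`.
#' @return An integer-valued `T x N` matrix.
#' @export
simulate_poisson_counts <- function(spec) {
  stopifnot(inherits(spec, "step_model_spec"))
  if (spec$noise != "poisson") stop("spec does not describe Poisson counts")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rates <- step_mean_profile(spec$T_len, spec$baseline, spec$cps, spec$weights)
  x <- matrix(stats::rpois(length(rates), rates), nrow(rates), ncol(rates))
  unname(x)
}

#' Square-root transform count data
#'
#' Elementwise square root, the standard variance-stabilizing transform for
#' Poisson counts (delta method: the transformed variance is approximately
#' 1/4 regardless of the rate), bringing count series closer to the Gaussian
#' step-model assumptions.
#'
#' @param x nonnegative numeric matrix or vector.
#' @return Object of the same shape with the square root applied.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0)) stop("square-root transform requires nonnegative entries")
  sqrt(x)
}

## coerce input to a T x N numeric matrix with finiteness checks
as_series_matrix <- function(x, min_len = 3L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("series must be finite")
  if (nrow(x) < min_len)
    stop(sprintf("series must have at least %d time steps", min_len))
  unname(x)
}
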