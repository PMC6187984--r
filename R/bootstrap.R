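## ---- block permutation ------------------------------------------------------

## B random block orders of 1..T split into consecutive blocks of size k
## (final block shorter when T mod k != 0); returns a T x B index matrix.
block_perm_indices <- function(T_len, k, B) {
  if (k < 1L || k > T_len) stop("block size must satisfy 1 <= k <= T")
  starts <- seq.int(1L, T_len, by = k)
  blocks <- lapply(starts, function(s) s:min(s + k - 1L, T_len))
  nb <- length(blocks)
  idx <- vapply(seq_len(B),
                function(i) unlist(blocks[sample.int(nb)], use.names = FALSE),
                integer(T_len))
  matrix(idx, T_len, B)
}

#' Block-permute a stationary series
#'
#' Splits the series into consecutive blocks of size `k` (the final block is
#' shorter if `T` is not a multiple of `k`), permutes the block order
#' uniformly at random and concatenates.  All columns of a multivariate
#' series are permuted with the same block order so cross-column alignment
#' is preserved.  Block permutation preserves temporal dependence up to lag
#' `k - 1`, which motivates `k = q + 1` for MA(q) noise; `k = 1` is an
#' ordinary permutation of time points.
#'
#' @param x numeric vector or matrix (rows = time steps).
#' @param k block size.
#' @return Permuted object of the same shape as `x`.
#' @export
block_permute <- function(x, k) {
  vec <- !is.matrix(x)
  xm <- if (vec) matrix(as.numeric(x), ncol = 1L) else x
  idx <- block_perm_indices(nrow(xm), as.integer(k), 1L)[, 1L]
  out <- xm[idx, , drop = FALSE]
  if (vec) out[, 1L] else out
}

#' Empirical bootstrap rejection threshold
#'
#' The `(1 - alpha)` quantile of the bootstrap statistics, implemented as
#' the `ceiling((1 - alpha) * B)`-th smallest order statistic, so that the
#' rejection rule `S >= threshold` has nominal level `alpha` under the
#' empirical distribution function.
#'
#' @param samples numeric vector of `B` bootstrap statistics.
#' @param alpha nominal significance level.
#' @return Scalar threshold.
#' @export
edf_threshold <- function(samples, alpha) {
  B <- length(samples)
  if (!B) stop("no bootstrap samples")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (alpha < 1 / B)
    warning("alpha below the bootstrap resolution 1/B")
  sort(samples)[ceiling((1 - alpha) * B)]
}

## CUSUM curves of B block-permuted copies of one column: T x B matrix
perm_cusum <- function(x0col, idx) {
  T_len <- nrow(idx)
  Z <- matrix(x0col[idx], T_len, ncol(idx))
  Z <- Z - rep(colMeans(Z), each = T_len)
  matrix(apply(Z, 2L, cumsum), T_len, ncol(idx))
}

## numerical floor below which a bending/CUSUM statistic is treated as no
## signal (guards exact-arithmetic acceptance on constant null series)
stat_floor <- function(x) {
  1e-8 * mean(apply(x, 2L, function(v) diff(range(v))))
}

## ---- CUSUM AMOC test --------------------------------------------------------

#' CUSUM at-most-one-change bootstrap test
#'
#' Locates a single candidate change point on the CUSUM curve
#' ([amoc_locator()]), estimates baseline and step from the segment means
#' before and after it, subtracts the estimated step to obtain a null-conform
#' series, and compares the maximum CUSUM statistic ([cusum_statistic()]) of
#' the observed series with the empirical distribution of the statistic over
#' `B` block-permuted copies of the null-conform series.
#'
#' @param x univariate numeric series.
#' @param alpha nominal significance level.
#' @param B number of block permutations.
#' @param k block size (`q + 1` for MA(q) noise; 1 for independent noise).
#' @param gamma locator exponent (see [amoc_locator()]); the test statistic
#'   itself is always the unweighted maximum excursion.
#' @param seed optional integer seed.
#' @param keep_null if `TRUE` the bootstrap statistics are returned in the
#'   result (for re-thresholding at other levels).
#' @return Object of class `"amoc_test"`: list with `changepoint` (`NA` when
#'   not significant), `candidate`, `statistic`, `threshold`, `p_value`,
#'   `significant`, step estimates `b` and `w`, and the test configuration.
#' @export
cusum_amoc_test <- function(x, alpha = 0.05, B = 1000L, k = 1L, gamma = 0,
                            seed = NULL, keep_null = FALSE) {
  x <- as_series_matrix(x)
  if (ncol(x) != 1L) stop("the AMOC test is defined for univariate series")
  if (B < 100L) stop("use at least 100 bootstrap permutations")
  if (!is.null(seed)) set.seed(seed)
  T_len <- nrow(x)
  xv <- x[, 1L]
  floor_S <- stat_floor(x) * T_len
  if (diff(range(xv)) == 0) {
    out <- list(changepoint = NA_integer_, candidate = NA_integer_,
                statistic = 0, threshold = 0, p_value = 1,
                significant = FALSE, b = xv[1L], w = 0,
                alpha = alpha, B = B, k = k, gamma = gamma)
    class(out) <- "amoc_test"
    return(out)
  }
  chat <- amoc_locator(xv, gamma)
  S <- cusum_statistic(xv)
  b_hat <- mean(xv[seq_len(chat)])
  w_hat <- mean(xv[(chat + 1L):T_len]) - b_hat
  x0 <- xv - w_hat * (seq_len(T_len) > chat)
  idx <- block_perm_indices(T_len, as.integer(k), as.integer(B))
  Yp <- perm_cusum(x0, idx)
  Si <- apply(abs(Yp[seq_len(T_len - 1L), , drop = FALSE]), 2L, max)
  thr <- edf_threshold(Si, alpha)
  sig <- (S >= thr) && (S > floor_S)
  out <- list(changepoint = if (sig) chat else NA_integer_,
              candidate = chat, statistic = S, threshold = thr,
              p_value = (1 + sum(Si >= S)) / (B + 1),
              significant = sig, b = b_hat, w = w_hat,
              alpha = alpha, B = B, k = k, gamma = gamma,
              null_samples = if (keep_null) Si else NULL)
  class(out) <- "amoc_test"
  out
}

#' @export
print.amoc_test <- function(x, ...) {
  cat("CUSUM AMOC block-permutation bootstrap test\n")
  if (is.na(x$candidate)) {
    cat("constant series: no candidate change point\n")
  } else {
    cat(sprintf("candidate c = %d, S = %.4g, threshold = %.4g, p = %.4g\n",
                x$candidate, x$statistic, x$threshold, x$p_value))
    cat(sprintf("%s at alpha = %g (B = %d, k = %d)\n",
                if (x$significant) "SIGNIFICANT" else "not significant",
                x$alpha, x$B, x$k))
    cat(sprintf("step estimates: b = %.4g, w = %.4g\n", x$b, x$w))
  }
  invisible(x)
}

## ---- PARCS bending statistic and bootstrap test ----------------------------

#' Bending statistic at a PARCS knot
#'
#' `S = |beta+_m + beta-_m|`, the absolute slope change of the fitted
#' piecewise-linear curve at knot `m` (its estimated step size; the bend
#' coefficient of the identified parameterization).  The statistic is zero
#' for a constant or purely linear fit through the knot; for multivariate
#' fits it is averaged over responses.
#'
#' @param object a fitted [parcs()] model.
#' @param m knot index (in rank order).
#' @return Nonnegative scalar.
#' @export
bending_statistic <- function(object, m = 1L) {
  stopifnot(inherits(object, "parcs"))
  if (m < 1L || m > length(object$knots)) stop("no such knot in the model")
  mean(abs(object$bend[m, ]))
}

#' Block-permutation bootstrap test for PARCS change points
#'
#' Sequentially tests the ranked knots of a fitted PARCS model.  The
#' null-conform series `x0` ([h0_series()]) is computed once from the full
#' fit.  For knot `m` (in rank order), the spline pairs of already-accepted
#' knots are regressed out of the CUSUM curve, the remaining knots
#' `m, ..., M` are refit to the residual curve, and the bending statistic at
#' knot `m` is compared with its empirical null distribution: each of `B`
#' block-permuted copies of `x0` is CUSUM-transformed and fitted with the
#' same remaining knot set, reading the bending statistic at the same knot.
#' Coefficients are re-estimated at every step.
#'
#' @param object a fitted [parcs()] model with at least one knot.
#' @param alpha nominal significance level.
#' @param B number of block permutations.
#' @param k block size, typically `q + 1` from [estimate_ma_order()].
#' @param seed optional integer seed.
#' @param keep_null if `TRUE`, per-knot bootstrap statistics are kept.
#' @return Object of class `"parcs_test"`: a per-knot decision table
#'   (`table`), the accepted locations `significant` (in rank order), the
#'   refit model restricted to the accepted knots (`model`), step estimates
#'   (`steps`), and the configuration.
#' @export
parcs_bootstrap_test <- function(object, alpha = 0.05, B = 1000L, k = 1L,
                                 seed = NULL, keep_null = FALSE) {
  stopifnot(inherits(object, "parcs"))
  M <- length(object$knots)
  if (M < 1L) stop("model has no knots to test")
  if (B < 100L) stop("use at least 100 bootstrap permutations")
  k <- as.integer(k)
  if (!is.null(seed)) set.seed(seed)
  T_len <- object$T_len
  N <- object$N
  Y <- object$y
  x0 <- h0_series(object)
  floor_S <- stat_floor(object$x)
  if (T_len / k < 7)
    warning("fewer than 7 blocks: permutation null is poorly resolved")
  accepted <- integer(0)
  rows <- vector("list", M)
  nulls <- if (keep_null) vector("list", M) else NULL
  for (m in seq_len(M)) {
    rem <- object$knots[m:M]
    Yr <- if (length(accepted)) Y - parcs_ols(Y, accepted)$fitted else Y
    fit_r <- parcs_ols(Yr, rem)
    S <- mean(abs(fit_r$bend[1L, ]))
    idx <- block_perm_indices(T_len, k, as.integer(B))
    ## null: each permuted copy of x0 is CUSUM-transformed and fitted with
    ## the SAME remaining knot set, reading the bend coefficient at the
    ## tested knot -- the statistic and its null are computed identically
    qx <- qr(parcs_basis(T_len, rem))
    bend <- numeric(B)
    for (n in seq_len(N)) {
      cf <- qr.coef(qx, perm_cusum(x0[, n], idx))
      bend <- bend + abs(cf[3L, ])   # bend coefficient of knot rem[1]
    }
    Si <- bend / N
    thr <- edf_threshold(Si, alpha)
    sig <- (S >= thr) && (S > floor_S)
    if (sig) accepted <- c(accepted, object$knots[m])
    rows[[m]] <- data.frame(rank = m, location = object$knots[m],
                            statistic = S, threshold = thr,
                            p_value = (1 + sum(Si >= S)) / (B + 1),
                            significant = sig)
    if (keep_null) nulls[[m]] <- Si
  }
  tab <- do.call(rbind, rows)
  final <- parcs(object$x, knots = sort(accepted))
  out <- list(table = tab, significant = accepted,
              model = final, steps = step_estimates(final),
              alpha = alpha, B = B, k = k,
              null_samples = nulls)
  class(out) <- "parcs_test"
  out
}

#' @export
print.parcs_test <- function(x, digits = 4L, ...) {
  cat(sprintf("PARCS block-permutation bootstrap test (alpha = %g, B = %d, k = %d)\n",
              x$alpha, x$B, x$k))
  tab <- x$table
  tab$statistic <- signif(tab$statistic, digits)
  tab$threshold <- signif(tab$threshold, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print(tab, row.names = FALSE)
  if (length(x$significant))
    cat("Significant change points:",
        paste(sort(x$significant), collapse = ", "), "\n")
  else cat("No significant change points\n")
  invisible(x)
}

## ---- end-to-end pipeline ----------------------------------------------------

#' Detect multiple change points with PARCS
#'
#' One-call pipeline: fit the PARCS model ([parcs()]), invert it to the
#' null-conform residual series ([h0_series()]), estimate the
#' moving-average noise order to set the bootstrap block size
#' (`k = q + 1`, [estimate_ma_order()]), and run the sequential
#' block-permutation test ([parcs_bootstrap_test()]).
#'
#' @param x numeric vector, matrix or data frame; rows are time steps.
#' @param M model order (maximum number of change points retained).
#' @param L forward bound on explored knots (default `3 * M`).
#' @param alpha nominal significance level of the bootstrap test.
#' @param B number of block permutations.
#' @param k block size, or `"auto"` to use `q_hat + 1` (capped at 10).
#' @param Q upper bound for the noise-order scan.
#' @param order_alpha level of the per-lag autocorrelation test.
#' @param seed optional integer seed covering the whole pipeline.
#' @return Object of class `"parcs_cps"`: the [parcs_bootstrap_test()]
#'   result augmented with `q` (estimated noise order), `k`, and the fitted
#'   full model (`full_model`).
#' @examples
#' spec <- step_model_spec(100, cps = c(20, 60), weights = c(2, -1),
#'                         sigma = 0.7, seed = 11)
#' res <- detect_changepoints(simulate_step_series(spec), M = 3,
#'                            B = 200, seed = 1)
#' res$significant
#' @export
detect_changepoints <- function(x, M = 1L, L = 3L * M, alpha = 0.05,
                                B = 1000L, k = "auto", Q = 9L,
                                order_alpha = 0.05, seed = NULL) {
  x <- as_series_matrix(x)
  if (!is.null(seed)) set.seed(seed)
  if (max(apply(x, 2L, function(v) diff(range(v)))) == 0) {
    out <- list(table = NULL, significant = integer(0),
                model = NULL, steps = NULL, q = 0L, k = 1L,
                full_model = NULL, alpha = alpha, B = B)
    class(out) <- c("parcs_cps", "parcs_test")
    return(out)
  }
  model <- parcs(x, M = M, L = L)
  q_hat <- estimate_ma_order(h0_series(model), Q = Q, alpha = order_alpha)
  k_use <- if (identical(k, "auto")) min(q_hat + 1L, 10L) else as.integer(k)
  test <- parcs_bootstrap_test(model, alpha = alpha, B = B, k = k_use)
  test$q <- q_hat
  test$full_model <- model
  class(test) <- c("parcs_cps", "parcs_test")
  test
}

#' @export
print.parcs_cps <- function(x, ...) {
  if (is.null(x$table)) {
    cat("Constant input: no change points\n")
    return(invisible(x))
  }
  cat(sprintf("Estimated MA noise order q = %d (block size k = %d)\n",
              x$q, x$k))
  NextMethod()
}
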