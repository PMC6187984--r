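## ---- spline basis and least-squares machinery ------------------------------

## the paired hinge splines anchored at a knot c:
## h+_{t,c} = t - c for t > c (else 0); h-_{t,c} = c - t for t < c (else 0).
## Their sum is |t - c| and their difference is t - c, so the span of the
## paired model {1, h+_m, h-_m}_{1:M} equals the span of the full-rank
## truncated-power basis {1, t, (t - c_m)_+}_{1:M} (the pairs share the
## slope direction, which makes the paired design rank deficient for
## M >= 2).  All least squares is therefore done on the truncated-power
## basis; the coefficient of the bend column (t - c_m)_+ is exactly the
## identified slope change beta+_m + beta-_m at the knot.
knot_pair <- function(T_len, c) {
  t_idx <- seq_len(T_len)
  list(h_plus = pmax(t_idx - c, 0), h_minus = pmax(c - t_idx, 0))
}

## full-rank design for a knot set: intercept only when empty, otherwise
## intercept, linear term, one bend column per knot
parcs_basis <- function(T_len, knots) {
  if (!length(knots)) return(matrix(1, T_len, 1L))
  t_idx <- seq_len(T_len)
  X <- matrix(0, T_len, 2L + length(knots))
  X[, 1L] <- 1
  X[, 2L] <- t_idx
  for (j in seq_along(knots)) X[, 2L + j] <- pmax(t_idx - knots[j], 0)
  X
}

## exact least squares of Y (T x N) on the knot basis; errors on rank
## deficiency (duplicate knots).  mse is the response-averaged
## mean-square-error (1/T residual sum of squares per response, averaged
## over responses); `bend` holds the slope-change coefficients (M x N).
parcs_ols <- function(Y, knots) {
  T_len <- nrow(Y)
  X <- parcs_basis(T_len, knots)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient spline design (degenerate knot set)")
  coef <- qr.coef(qx, Y)
  coef <- matrix(coef, ncol(X), ncol(Y))
  fitted <- X %*% coef
  res <- Y - fitted
  M <- length(knots)
  rownames(coef) <- if (M) c("(Intercept)", "t", paste0("bend", knots))
                    else "(Intercept)"
  list(knots = knots, coefficients = coef, fitted = fitted, residuals = res,
       mse = mean(res^2),
       bend = if (M) coef[2L + seq_len(M), , drop = FALSE]
              else matrix(0, 0L, ncol(Y)))
}

## response-averaged mse for a knot set (no coefficient bookkeeping)
parcs_mse <- function(Y, knots) {
  X <- parcs_basis(nrow(Y), knots)
  mean(qr.resid(qr(X), Y)^2)
}

## ---- forward selection ------------------------------------------------------

## Greedy forward sweep: starting from the intercept-only model, add the
## knot pair that reduces the response-averaged mse the most, L times.  The
## scan over all unused candidates in 2:(T-1) is vectorized: every bend
## column is orthogonalized against the current design at once, and the
## exact residual-sum-of-squares reduction is read off in closed form (a
## 2x2 solve on the first step, where the pair also contributes the slope
## direction; a single projection afterwards).
parcs_forward <- function(Y, L, tol = 1e-12) {
  T_len <- nrow(Y)
  if (L + 2L >= T_len) stop("forward bound L too large for the series length")
  cand <- 2:(T_len - 1L)
  t_idx <- seq_len(T_len)
  Hb <- outer(t_idx, cand, function(t, c) pmax(t - c, 0))
  knots <- integer(0)
  Q <- matrix(1 / sqrt(T_len), T_len, 1L)
  R <- Y - Q %*% crossprod(Q, Y)
  mse_path <- numeric(L)
  for (m in seq_len(L)) {
    U1 <- Hb - Q %*% crossprod(Q, Hb)
    g11 <- colSums(U1 * U1)
    B1 <- crossprod(U1, R)                     # C x N
    if (m == 1L) {
      u2 <- t_idx - mean(t_idx)                # slope, orthogonal to 1
      g22 <- sum(u2 * u2)
      g12 <- colSums(U1 * u2)
      det <- g11 * g22 - g12 * g12
      B2 <- crossprod(matrix(u2), R)           # 1 x N
      red <- (g22 * rowSums(B1 * B1) -
                2 * g12 * drop(B1 %*% t(B2)) +
                g11 * sum(B2 * B2)) / det
      bad <- !is.finite(red) |
        det <= 1e-10 * pmax(g11 * g22, .Machine$double.xmin)
    } else {
      red <- rowSums(B1 * B1) / g11
      bad <- (cand %in% knots) | !is.finite(red) |
        g11 <= 1e-10 * colSums(Hb * Hb)
    }
    red[bad] <- -Inf
    best <- max(red)
    if (!is.finite(best)) stop("no admissible candidate knot left")
    pick <- which(red >= best - tol * max(abs(best), 1e-300))[1L]
    knots <- c(knots, cand[pick])
    X <- parcs_basis(T_len, knots)
    Q <- qr.Q(qr(X))
    R <- Y - Q %*% crossprod(Q, Y)
    mse_path[m] <- mean(R^2)
  }
  list(knots = knots, mse_path = mse_path)
}

## ---- backward pruning and ranking ------------------------------------------

## drop knots greedily (smallest mse increase first) until M remain;
## coefficients are re-estimated from scratch after each removal
parcs_prune <- function(Y, knots, M) {
  if (M > length(knots)) stop("cannot prune to more knots than present")
  while (length(knots) > M) {
    mses <- vapply(seq_along(knots),
                   function(i) parcs_mse(Y, knots[-i]), 0)
    knots <- knots[-which.min(mses)]
  }
  knots
}

## continue the greedy removal from M down to 0 to rank knots by explained
## variance: the first knot removed explains the least and is ranked last
parcs_rank <- function(Y, knots) {
  M <- length(knots)
  ranked <- integer(M)
  ks <- knots
  for (m in rev(seq_len(M))) {
    mses <- vapply(seq_along(ks), function(i) parcs_mse(Y, ks[-i]), 0)
    i <- which.min(mses)
    ranked[m] <- ks[i]
    ks <- ks[-i]
  }
  ranked
}

## ---- user-facing fit --------------------------------------------------------

#' Fit a PARCS change point model
#'
#' Fits the order-`M` PARCS model: the CUSUM transformation of the series is
#' approximated by a piecewise-linear curve built from `M` pairs of hinge
#' splines, each pair anchored at one candidate change point (knot).  Knots
#' are placed adaptively by a forward sweep up to `L` knots (each step adds
#' the spline pair reducing the response-averaged residual mean-square-error
#' the most), pruned back to `M` knots (each step removes the pair whose
#' removal costs least), and finally ranked by explained variance, so that
#' `knots[1]` is the strongest candidate change point.  For multivariate
#' input the responses share the knots but get their own coefficients, and
#' selection uses the mean-square-error averaged over responses.
#'
#' Internally the fit uses the equivalent full-rank truncated-power
#' parameterization of the paired-spline span (see the package vignette);
#' the reported per-knot `bend` coefficients are the identified slope
#' changes `beta+_m + beta-_m`, which on the original series scale are the
#' estimated step sizes.
#'
#' Alternatively a fixed knot set can be supplied via `knots`, in which case
#' only the least-squares fit and the explained-variance ranking are
#' performed.
#'
#' @param x numeric vector, matrix or data frame; rows are time steps.
#' @param M number of change points to retain (the model order).
#' @param L forward bound on the number of knots explored; the default `3*M`
#'   follows the usual 2-3 times `M` heuristic for adaptive regression
#'   splines.
#' @param knots optional fixed knot locations in `2:(T-1)` (overrides the
#'   forward/backward search).
#' @return An object of class `"parcs"` with components `knots` (ranked),
#'   `coefficients`, `fitted` (fitted CUSUM curve), `residuals`, `mse`,
#'   `bend` (M x N slope changes), the input series `x`, the curve `y`,
#'   `x_mean`, and bookkeeping fields.  Methods: [print.parcs()],
#'   [summary.parcs()], [coef.parcs()], [fitted.parcs()],
#'   [residuals.parcs()], [predict.parcs()], [plot.parcs()],
#'   [simulate.parcs()], [step_estimates()].
#' @examples
#' spec <- step_model_spec(100, cps = c(20, 60), weights = c(2, -1),
#'                         sigma = 0.5, seed = 7)
#' fit <- parcs(simulate_step_series(spec), M = 2)
#' fit$knots
#' @export
parcs <- function(x, M = 1L, L = 3L * M, knots = NULL) {
  x <- as_series_matrix(x)
  cc <- cusum_transform(x)
  Y <- cc$y
  T_len <- cc$T_len
  degenerate <- max(abs(Y)) <= 1e-12 * T_len * max(abs(x), 1)
  forward_path <- NULL
  if (is.null(knots)) {
    M <- as.integer(M)
    L <- as.integer(L)
    if (M < 0L) stop("model order M must be nonnegative")
    if (L < M) stop("forward bound L must be at least M")
    if (M == 0L) {
      knots <- integer(0)
    } else {
      if (degenerate) warning("constant series: knot placement is arbitrary")
      fw <- parcs_forward(Y, L)
      knots <- parcs_prune(Y, fw$knots, M)
      forward_path <- fw$mse_path
    }
  } else {
    knots <- as.integer(knots)
    if (anyDuplicated(knots)) stop("knots must be distinct")
    if (length(knots) && (min(knots) < 2L || max(knots) > T_len - 1L))
      stop("knots must lie in 2:(T-1)")
    M <- length(knots)
    L <- M
  }
  ranked <- parcs_rank(Y, knots)
  fit <- parcs_ols(Y, ranked)
  structure(
    c(fit,
      list(x = x, y = Y, x_mean = cc$x_mean, T_len = T_len, N = cc$N,
           M = M, L = L, degenerate = degenerate,
           forward_mse = forward_path,
           call = match.call())),
    class = "parcs")
}
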