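#' Center bias of a change point estimate
#'
#' Signed displacement of an estimated change point toward the middle of the
#' series: `cb = (2 * H(c - T/2) - 1) * (c - chat)` with `H` the discrete
#' Heaviside function (`H(i) = 1` iff `i > 0`).  Positive values mean the
#' estimate fell on the side of the true change point facing the series
#' center, the systematic direction of CUSUM localization error for
#' peripheral change points.
#'
#' @param c_true true change point location (1-based).
#' @param c_hat estimated location.
#' @param T_len series length.
#' @return Signed bias in time steps (vectorized over `c_hat`).
#' @examples
#' center_bias(20, 24, 100)  # +4: estimate displaced toward the center
#' center_bias(80, 76, 100)  # +4 by symmetry
#' @export
center_bias <- function(c_true, c_hat, T_len) {
  if (any(c_true < 1 | c_true > T_len) || any(c_hat < 1 | c_hat > T_len))
    stop("change points must lie in 1..T")
  (2 * (c_true - T_len / 2 > 0) - 1) * (c_true - c_hat)
}

#' Accuracy score of a change point detector
#'
#' Correct-detection rate (percent of replicate realizations with at least
#' one significant detection within a +/- 5% of series length window around
#' the true change point), adjusted for false discoveries by subtracting the
#' empirical type-I error rate divided by the model order:
#' `score = hit_rate - alpha_hat / M`.
#'
#' @param detections list with one numeric vector of significant change
#'   point locations per realization (possibly empty vectors).
#' @param c_true true change point location.
#' @param T_len series length (sets the `0.05 * T_len` hit window).
#' @param M model order used for the adjustment.
#' @param alpha_hat empirical type-I error rate in percent (see
#'   [summarize_detections()]).
#' @return Accuracy score in percent.
#' @export
accuracy_score <- function(detections, c_true, T_len, M, alpha_hat = 0) {
  if (M <= 0) stop("model order M must be positive")
  if (!length(detections)) stop("need at least one realization")
  win <- 0.05 * T_len
  hit <- vapply(detections, function(d) {
    length(d) > 0 && any(abs(d - c_true) <= win)
  }, logical(1))
  100 * mean(hit) - alpha_hat / M
}

#' Summarize replicate detections against ground truth
#'
#' Computes the error rates and accuracy scores used to benchmark multiple
#' change point detectors over replicate simulations.  Per realization, a
#' type-I event is at least one significant detection farther than 5% of the
#' series length from every true change point; a type-II event is at least
#' one true change point with no significant detection within that window.
#' Accuracy scores per true change point subtract the empirical type-I rate
#' divided by the model order from the hit rate ([accuracy_score()]).
#'
#' @param detections list of numeric vectors of significant locations, one
#'   per realization.
#' @param cps true change point locations (may be empty for null series).
#' @param T_len series length.
#' @param M model order used for the accuracy adjustment.
#' @return A list with fields `type1_rate`, `type2_rate` (percent),
#'   `accuracy` (named vector, one score per true change point),
#'   `hit_rate` (unadjusted, percent), `n_detected` (integer vector of
#'   detection counts per realization) and `exactly` (function-free table of
#'   detection-count frequencies).
#' @export
summarize_detections <- function(detections, cps, T_len, M) {
  R <- length(detections)
  if (!R) stop("need at least one realization")
  win <- 0.05 * T_len
  false_disc <- vapply(detections, function(d) {
    length(d) > 0 &&
      any(vapply(d, function(ci) all(abs(ci - cps) > win) || !length(cps),
                 logical(1)))
  }, logical(1))
  miss <- vapply(detections, function(d) {
    length(cps) > 0 &&
      any(vapply(cps, function(ct) !length(d) || all(abs(d - ct) > win),
                 logical(1)))
  }, logical(1))
  type1 <- 100 * mean(false_disc)
  type2 <- 100 * mean(miss)
  acc <- if (length(cps)) {
    stats::setNames(
      vapply(cps, function(ct)
        accuracy_score(detections, ct, T_len, M, alpha_hat = type1), 0),
      paste0("c", cps))
  } else numeric(0)
  hits <- if (length(cps)) {
    stats::setNames(
      vapply(cps, function(ct) {
        100 * mean(vapply(detections, function(d)
          length(d) > 0 && any(abs(d - ct) <= win), logical(1)))
      }, 0), paste0("c", cps))
  } else numeric(0)
  n_det <- vapply(detections, length, 0L)
  list(type1_rate = type1, type2_rate = type2, accuracy = acc,
       hit_rate = hits, n_detected = n_det,
       count_table = table(factor(n_det, levels = 0:max(c(n_det, length(cps))))))
}
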