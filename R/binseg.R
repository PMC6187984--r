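#' CUSUM binary segmentation baseline
#'
#' Classic recursive baseline for multiple change points: the bootstrap
#' CUSUM test ([cusum_amoc_test()]) is applied to the full series; upon a
#' significant detection the series is partitioned at the detected point and
#' the test recurses on the left and right segments.  Recursion stops on a
#' non-significant test, when the partition depth reaches `max_depth`, or
#' when a segment is shorter than `min_len` (bootstrapping very short
#' segments is statistically meaningless).  Each segment re-estimates its
#' own baseline and step, and uses block size 1 (the baseline is intended
#' for independent noise, where segmentwise block sizing is well defined).
#'
#' @param x univariate numeric series.
#' @param alpha nominal significance level per segment test.
#' @param B number of permutations per segment test.
#' @param gamma locator exponent passed to [cusum_amoc_test()].
#' @param max_depth maximum number of partition levels (`max_depth = 1`
#'   allows up to three detections: the root plus one per child segment).
#' @param min_len minimum segment length that is still tested.
#' @param seed optional integer seed.
#' @return Object of class `"binseg"`: a data frame `table` with one row per
#'   significant detection (`location` in absolute 1-based coordinates,
#'   `lo`, `hi`, `depth`, `statistic`, `threshold`, `p_value`) and the
#'   sorted locations in `significant`.
#' @export
binseg_detect <- function(x, alpha = 0.05, B = 1000L, gamma = 0,
                          max_depth = 1L, min_len = 8L, seed = NULL) {
  x <- as_series_matrix(x)
  if (ncol(x) != 1L) stop("binary segmentation is defined for univariate series")
  if (min_len < 4L) stop("min_len must be at least 4")
  if (!is.null(seed)) set.seed(seed)
  xv <- x[, 1L]
  rows <- list()
  recurse <- function(lo, hi, depth) {
    len <- hi - lo + 1L
    if (len < min_len) return(invisible())
    seg <- xv[lo:hi]
    if (diff(range(seg)) == 0) return(invisible())
    tst <- cusum_amoc_test(seg, alpha = alpha, B = B, k = 1L, gamma = gamma)
    if (!tst$significant) return(invisible())
    cp <- lo - 1L + tst$candidate
    rows[[length(rows) + 1L]] <<- data.frame(
      location = cp, lo = lo, hi = hi, depth = depth,
      statistic = tst$statistic, threshold = tst$threshold,
      p_value = tst$p_value)
    if (depth < max_depth) {
      recurse(lo, cp, depth + 1L)
      recurse(cp + 1L, hi, depth + 1L)
    }
  }
  recurse(1L, length(xv), 0L)
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(location = integer(0), lo = integer(0), hi = integer(0),
               depth = integer(0), statistic = numeric(0),
               threshold = numeric(0), p_value = numeric(0))
  structure(list(table = tab, significant = sort(tab$location),
                 alpha = alpha, B = B, max_depth = max_depth,
                 min_len = min_len),
            class = "binseg")
}

#' @export
print.binseg <- function(x, ...) {
  cat(sprintf("CUSUM binary segmentation (alpha = %g, B = %d, max depth = %d)\n",
              x$alpha, x$B, x$max_depth))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  else cat("No significant change points\n")
  invisible(x)
}
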