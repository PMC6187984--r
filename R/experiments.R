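## ---- replicate seed derivation ---------------------------------------------

## independent per-replicate seeds derived from one master seed, so that
## replicate r is reproducible in isolation and results do not depend on
## evaluation order
replicate_seeds <- function(seed, R) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, R)
}

## ---- AMOC benchmark ---------------------------------------------------------

#' Single change point benchmark over replicate simulations
#'
#' Simulates univariate step series and runs the CUSUM bootstrap test and/or
#' the order-1 PARCS bootstrap test on each realization, recording whether a
#' significant change point was found and where.
#'
#' @param c_true vector of true change point locations; one simulation cell
#'   per entry (`NA` entries simulate pure noise, the no-change null).
#' @param T_len series length.
#' @param w step size.
#' @param sigma innovation standard deviation.
#' @param kappas MA noise coefficients (empty = white noise).
#' @param R replicates per cell.
#' @param B bootstrap permutations.
#' @param alpha nominal level for both tests.
#' @param methods subset of `c("cusum", "parcs")`.
#' @param gamma CUSUM locator exponent (0.5 gives the maximum likelihood
#'   locator).
#' @param k block size used by both tests.
#' @param seed master seed.
#' @return Data frame with one row per replicate x method: `c_true`, `rep`,
#'   `method`, `detected`, `c_hat` (NA when not significant) and
#'   `center_bias`.
#' @export
run_amoc_experiment <- function(c_true, T_len = 100L, w = 1, sigma = 1,
                                kappas = numeric(), R = 200L, B = 1000L,
                                alpha = 0.05, methods = c("cusum", "parcs"),
                                gamma = 0, k = 1L, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (ci in c_true) {
    seeds <- replicate_seeds(seed + match(ci, c_true), R)
    for (r in seq_len(R)) {
      set.seed(seeds[r])
      spec <- if (is.na(ci))
        step_model_spec(T_len, sigma = sigma, kappas = kappas)
      else
        step_model_spec(T_len, cps = ci, weights = w, sigma = sigma,
                        kappas = kappas)
      x <- simulate_step_series(spec)
      for (meth in methods) {
        if (meth == "cusum") {
          tst <- cusum_amoc_test(x, alpha = alpha, B = B, k = k,
                                 gamma = gamma)
          det <- tst$significant
          chat <- tst$changepoint
        } else {
          fit <- parcs(x, M = 1L, L = 3L)
          tst <- parcs_bootstrap_test(fit, alpha = alpha, B = B, k = k)
          det <- length(tst$significant) > 0L
          chat <- if (det) tst$significant[1L] else NA_integer_
        }
        out[[length(out) + 1L]] <- data.frame(
          c_true = ci, rep = r, method = meth, detected = det,
          c_hat = chat,
          center_bias = if (det && !is.na(ci))
            center_bias(ci, chat, T_len) else NA_real_)
      }
    }
  }
  do.call(rbind, out)
}

#' Empirical size of the bootstrap tests under the no-change null
#'
#' Simulates pure-noise series and evaluates the rejection rate of the CUSUM
#' and/or PARCS bootstrap tests over a grid of nominal levels, re-using one
#' set of bootstrap statistics per realization.
#'
#' @inheritParams run_amoc_experiment
#' @param alphas vector of nominal levels at which to read off rejection
#'   rates.
#' @return Data frame with `method`, `alpha`, `rate` (percent of replicates
#'   rejecting the true null).
#' @export
run_h0_experiment <- function(T_len = 100L, sigma = 1, kappas = numeric(),
                              R = 500L, B = 1000L, alphas = 0.05,
                              methods = c("cusum", "parcs"), k = 1L,
                              seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  seeds <- replicate_seeds(seed, R)
  rej <- array(0L, c(length(methods), length(alphas)),
               dimnames = list(methods, NULL))
  for (r in seq_len(R)) {
    set.seed(seeds[r])
    spec <- step_model_spec(T_len, sigma = sigma, kappas = kappas)
    x <- simulate_step_series(spec)
    for (meth in methods) {
      if (meth == "cusum") {
        tst <- cusum_amoc_test(x, alpha = min(alphas), B = B, k = k,
                               keep_null = TRUE)
        S <- tst$statistic
        Si <- tst$null_samples
      } else {
        fit <- parcs(x, M = 1L, L = 3L)
        tst <- parcs_bootstrap_test(fit, alpha = min(alphas), B = B, k = k,
                                    keep_null = TRUE)
        S <- tst$table$statistic[1L]
        Si <- tst$null_samples[[1L]]
      }
      for (a in seq_along(alphas))
        rej[meth, a] <- rej[meth, a] +
          (S >= edf_threshold(Si, alphas[a]))
    }
  }
  expand <- expand.grid(method = methods, alpha = alphas,
                        stringsAsFactors = FALSE)
  expand$rate <- 100 * mapply(function(m, a)
    rej[m, match(a, alphas)], expand$method, expand$alpha) / R
  expand
}

## ---- multiple change point benchmark ---------------------------------------

#' Multiple change point benchmark over replicate simulations
#'
#' Simulates step series with two (or more) common change points and runs
#' the full PARCS pipeline ([detect_changepoints()]) on each realization.
#' Covers the univariate white-noise and MA-noise comparisons, and the
#' multivariate Gaussian and Poisson settings.
#'
#' @param weights step weight matrix (M x N) or vector (univariate).
#' @param baseline per-covariate baselines.
#' @param cps true change point locations.
#' @param T_len series length.
#' @param N number of covariates.
#' @param sigma innovation standard deviation (Gaussian noise).
#' @param kappas MA coefficients (empty = white noise).
#' @param noise `"gaussian_ma"` or `"poisson"`; Poisson counts are
#'   square-root transformed before fitting.
#' @param R replicates.
#' @param B bootstrap permutations.
#' @param alpha nominal level of the bootstrap test.
#' @param M,L PARCS model order and forward bound.
#' @param k block size, or `"auto"` for `q_hat + 1` from the residual
#'   autocorrelation scan.
#' @param Q upper bound of the noise-order scan.
#' @param seed master seed.
#' @return A list with `detections` (list of significant-location vectors,
#'   one per replicate), `q_hat` (estimated noise orders), `summary`
#'   (from [summarize_detections()]) and `exact_rate` (percent of
#'   replicates with exactly `length(cps)` significant change points).
#' @export
run_multicp_experiment <- function(weights, baseline = 0, cps = c(20L, 60L),
                                   T_len = 100L, N = 1L, sigma = 1,
                                   kappas = numeric(),
                                   noise = c("gaussian_ma", "poisson"),
                                   R = 200L, B = 1000L, alpha = 0.05,
                                   M = 3L, L = 3L * M, k = 1L, Q = 9L,
                                   seed = 1L) {
  noise <- match.arg(noise)
  seeds <- replicate_seeds(seed, R)
  detections <- vector("list", R)
  q_hat <- integer(R)
  for (r in seq_len(R)) {
    set.seed(seeds[r])
    spec <- step_model_spec(T_len, N = N, baseline = baseline, cps = cps,
                            weights = weights, noise = noise, sigma = sigma,
                            kappas = if (noise == "gaussian_ma") kappas
                                     else numeric())
    x <- if (noise == "poisson") sqrt_transform(simulate_poisson_counts(spec))
         else simulate_step_series(spec)
    res <- detect_changepoints(x, M = M, L = L, alpha = alpha, B = B,
                               k = k, Q = Q)
    detections[[r]] <- sort(res$significant)
    q_hat[r] <- res$q
  }
  sm <- summarize_detections(detections, cps, T_len, M)
  list(detections = detections, q_hat = q_hat, summary = sm,
       exact_rate = 100 * mean(sm$n_detected == length(cps)))
}

#' Binary segmentation benchmark over replicate simulations
#'
#' Companion to [run_multicp_experiment()] running the CUSUM binary
#' segmentation baseline ([binseg_detect()]) on the same generative
#' scenarios (univariate, white noise).
#'
#' @inheritParams run_multicp_experiment
#' @param max_depth maximum partition depth.
#' @return A list with `detections` and `summary` as in
#'   [run_multicp_experiment()] (accuracy adjusted with the number of true
#'   change points plus one as the effective model order).
#' @export
run_binseg_experiment <- function(weights, cps = c(20L, 60L), T_len = 100L,
                                  sigma = 1, R = 200L, B = 1000L,
                                  alpha = 0.05, max_depth = 1L, seed = 1L) {
  seeds <- replicate_seeds(seed, R)
  detections <- vector("list", R)
  for (r in seq_len(R)) {
    set.seed(seeds[r])
    spec <- step_model_spec(T_len, cps = cps, weights = weights,
                            sigma = sigma)
    x <- simulate_step_series(spec)
    detections[[r]] <- binseg_detect(x, alpha = alpha, B = B,
                                     max_depth = max_depth)$significant
  }
  sm <- summarize_detections(detections, cps, T_len, M = length(cps) + 1L)
  list(detections = detections, summary = sm,
       exact_rate = 100 * mean(sm$n_detected == length(cps)))
}

## ---- configuration-driven runner -------------------------------------------

#' Run a named simulation experiment from a configuration list
#'
#' Thin dispatcher over the experiment drivers, suitable for running from a
#' configuration file: `cfg$scenario` selects the experiment family and the
#' remaining entries are passed through to the driver.
#'
#' Recognized scenarios: `"amoc"` ([run_amoc_experiment()]), `"h0"`
#' ([run_h0_experiment()]), `"multicp"` ([run_multicp_experiment()]),
#' `"binseg"` ([run_binseg_experiment()]),
#' `"multivariate_gaussian"` and `"multivariate_poisson"` (the nine-covariate
#' benchmarks with their standard parameter sets:
#' `b = (0,0,0,2,2,2,0,1,2)` resp. `(1,1,1,3,3,3,1,2,1)`, change points at
#' 20 and 60 with weight rows `(1,2,2,-2,0,0,0,0,0)` and
#' `(2,1,-1,0,1,-1,0,0,0)`).
#'
#' @param cfg named list with at least `scenario`; other entries override
#'   driver defaults (e.g. `R`, `B`, `alpha`, `seed`).
#' @return The driver's return value.
#' @export
run_experiment <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$scenario))
  scenario <- cfg$scenario
  cfg$scenario <- NULL
  w1 <- c(1, 2, 2, -2, 0, 0, 0, 0, 0)
  w2 <- c(2, 1, -1, 0, 1, -1, 0, 0, 0)
  switch(scenario,
    amoc = do.call(run_amoc_experiment, cfg),
    h0 = do.call(run_h0_experiment, cfg),
    multicp = do.call(run_multicp_experiment, cfg),
    binseg = do.call(run_binseg_experiment, cfg),
    multivariate_gaussian = do.call(run_multicp_experiment, utils::modifyList(
      list(weights = rbind(w1, w2), baseline = c(0, 0, 0, 2, 2, 2, 0, 1, 2),
           N = 9L, sigma = 1, noise = "gaussian_ma", k = 1L), cfg)),
    multivariate_poisson = do.call(run_multicp_experiment, utils::modifyList(
      list(weights = rbind(w1, w2), baseline = c(1, 1, 1, 3, 3, 3, 1, 2, 1),
           N = 9L, noise = "poisson", k = 1L), cfg)),
    stop("unknown scenario: ", scenario))
}

## ---- series I/O -------------------------------------------------------------

#' Read a time series matrix from delimited text
#'
#' Rows are time steps, columns are covariates.  With `header = "auto"` the
#' first line is treated as a header when any of its fields is non-numeric.
#'
#' @param path file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @param header `TRUE`, `FALSE` or `"auto"`.
#' @return Numeric `T x N` matrix.
#' @export
read_series <- function(path, sep = ",", header = "auto") {
  if (identical(header, "auto")) {
    first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
    header <- anyNA(suppressWarnings(as.numeric(first)))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "numeric")
  if (!nrow(df)) stop("empty series file")
  as_series_matrix(as.matrix(df))
}

#' Write a time series matrix to CSV
#'
#' @param x numeric vector or matrix (rows = time steps).
#' @param path output file path.
#' @export
write_series <- function(x, path) {
  x <- as_series_matrix(x)
  xc <- apply(x, 2L, function(v) sprintf("%.17g", v))  # lossless round trip
  xc <- matrix(xc, nrow(x), ncol(x))
  colnames(xc) <- paste0("series", seq_len(ncol(x)))
  utils::write.table(xc, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results table to CSV
#'
#' @param table data frame of experiment results.
#' @param path output file path.
#' @export
write_results <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
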