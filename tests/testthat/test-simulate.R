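test_that("noiseless step series follows the Heaviside convention exactly", {
  spec <- step_model_spec(100, cps = 20, weights = 1, sigma = 0)
  x <- simulate_step_series(spec)
  expect_identical(dim(x), c(100L, 1L))
  expect_true(all(x[1:20, 1] == 0))   # change takes effect from t = c + 1
  expect_true(all(x[21:100, 1] == 1))
})

test_that("segment means of the nine-covariate Gaussian benchmark match the profile", {
  b <- c(0, 0, 0, 2, 2, 2, 0, 1, 2)
  w1 <- c(1, 2, 2, -2, 0, 0, 0, 0, 0)
  w2 <- c(2, 1, -1, 0, 1, -1, 0, 0, 0)
  reps <- 100
  acc <- matrix(0, 100, 9)
  for (r in seq_len(reps)) {
    spec <- step_model_spec(100, N = 9, baseline = b, cps = c(20, 60),
                            weights = rbind(w1, w2), sigma = 1,
                            seed = 5000 + r)
    acc <- acc + simulate_step_series(spec)
  }
  acc <- acc / reps
  seg_means <- rbind(colMeans(acc[1:20, ]), colMeans(acc[21:60, ]),
                     colMeans(acc[61:100, ]))
  expected <- rbind(b, b + w1, b + w1 + w2)
  expect_lt(max(abs(seg_means - expected)), 0.12)  # ~3 MC s.e.
})

test_that("MA noise has the closed-form variance and autocovariance", {
  sigma <- 0.7
  kap <- c(-0.5 / sigma, 0.4 / sigma)
  spec <- step_model_spec(1e5, sigma = sigma, kappas = kap, seed = 42)
  x <- simulate_step_series(spec)[, 1]
  v_theory <- sigma^2 * (1 + sum(kap^2))
  expect_lt(abs(var(x) - v_theory) / v_theory, 0.02)
  # autocovariance at lag tau is sigma^2 * sum_j kappa_j kappa_{j+tau}
  kfull <- c(1, kap)
  for (tau in 1:3) {
    g_theory <- if (tau <= 2)
      sigma^2 * sum(kfull[1:(3 - tau)] * kfull[(1 + tau):3]) else 0
    g_hat <- mean((x[1:(1e5 - tau)] - mean(x)) * (x[(1 + tau):1e5] - mean(x)))
    expect_lt(abs(g_hat - g_theory), 3 * sqrt(2 / 1e5) * v_theory)
  }
})

test_that("simulation is deterministic given spec and seed", {
  spec <- step_model_spec(200, N = 3, baseline = 1:3, cps = c(50, 120),
                          weights = matrix(rnorm(6), 2), sigma = 0.5,
                          kappas = 0.3, seed = 77)
  expect_identical(simulate_step_series(spec), simulate_step_series(spec))
  psp <- step_model_spec(150, N = 2, baseline = 2, cps = 40, weights = c(1, 3),
                         noise = "poisson", seed = 9)
  expect_identical(simulate_poisson_counts(psp), simulate_poisson_counts(psp))
})

test_that("Poisson counts follow the piecewise rate profile", {
  spec <- step_model_spec(1e5, baseline = 1, noise = "poisson", seed = 3)
  x <- simulate_poisson_counts(spec)[, 1]
  expect_true(all(x == floor(x)))
  expect_lt(abs(mean(x) - 1), 0.03)
  expect_lt(abs(var(x) - 1), 0.05)
  # rate-zero segment is identically zero
  z <- step_model_spec(100, baseline = 1, cps = 50, weights = -1,
                       noise = "poisson", seed = 4)
  xz <- simulate_poisson_counts(z)
  expect_true(all(xz[51:100, 1] == 0))
  # benchmark rate profile, averaged over replicates
  b <- c(1, 1, 1, 3, 3, 3, 1, 2, 1)
  w1 <- c(1, 2, 2, -2, 0, 0, 0, 0, 0)
  w2 <- c(2, 1, -1, 0, 1, -1, 0, 0, 0)
  acc <- matrix(0, 100, 9)
  for (r in 1:100) {
    sp <- step_model_spec(100, N = 9, baseline = b, cps = c(20, 60),
                          weights = rbind(w1, w2), noise = "poisson",
                          seed = 7000 + r)
    acc <- acc + simulate_poisson_counts(sp)
  }
  acc <- acc / 100
  seg <- rbind(colMeans(acc[1:20, ]), colMeans(acc[21:60, ]),
               colMeans(acc[61:100, ]))
  expect_lt(max(abs(seg - rbind(b, b + w1, b + w1 + w2))), 0.2)
})

test_that("square-root transform stabilizes Poisson variance", {
  expect_identical(sqrt_transform(c(0, 4, 9)), c(0, 2, 3))
  expect_error(sqrt_transform(-1), "nonnegative")
  # exact variances of sqrt(Poisson(lambda)) by enumeration: 0.3056, 0.2655,
  # 0.2565 for lambda = 4, 8, 16 -- near the delta-method value 1/4, and
  # nearly constant while the raw variance triples with each step
  set.seed(11)
  exact <- c(`4` = 0.3056, `8` = 0.2655, `16` = 0.2565)
  vs <- vapply(c(4, 8, 16), function(lam) var(sqrt(rpois(2e4, lam))), 0)
  expect_lt(max(abs(vs - exact)), 0.02)
  expect_lt(diff(range(vs)), 0.07)
})

test_that("invalid step model specifications are rejected", {
  expect_error(step_model_spec(100, cps = c(60, 20), weights = c(1, 1)),
               "increasing")
  expect_error(step_model_spec(100, cps = 100, weights = 1), "inside")
  expect_error(step_model_spec(100, sigma = -1), "nonnegative")
  expect_error(step_model_spec(100, cps = 20, weights = -2, baseline = 1,
                               noise = "poisson"), "nonnegative")
  expect_error(step_model_spec(100, cps = 20, weights = matrix(1, 2, 1)),
               "one row per change point")
  expect_error(simulate_poisson_counts(step_model_spec(100, sigma = 1)),
               "Poisson")
})

test_that("center bias is signed toward the series center and antisymmetric", {
  expect_identical(center_bias(20, 24, 100), 4)
  expect_identical(center_bias(80, 76, 100), 4)
  expect_identical(center_bias(60, 64, 100), -4)
  set.seed(2)
  for (i in 1:50) {
    # mirror symmetry: reflecting both the true and the estimated point
    # about the series midpoint flips the side indicator and the
    # difference, leaving the center bias unchanged (cf. the +4/+4 pair
    # above); even T keeps the reflection off the exact midpoint
    T_len <- 2 * sample(10:100, 1)
    c_true <- sample(T_len, 1)
    c_hat <- sample(T_len, 1)
    cb <- center_bias(c_true, c_hat, T_len)
    expect_equal(center_bias(T_len + 1 - c_true, T_len + 1 - c_hat, T_len), cb)
  }
  expect_error(center_bias(0, 5, 10), "1..T")
})

test_that("accuracy score is the windowed hit rate minus alpha_hat / M", {
  hits <- replicate(10, 20 + sample(-5:5, 1), simplify = FALSE)
  expect_equal(accuracy_score(hits, 20, 100, M = 1), 100)
  expect_equal(accuracy_score(rep(list(numeric(0)), 10), 20, 100, M = 3), 0)
  expect_equal(accuracy_score(hits, 20, 100, M = 3, alpha_hat = 9), 97)
  expect_error(accuracy_score(hits, 20, 100, M = 0), "positive")
})

test_that("detection summaries count false discoveries and misses per realization", {
  det <- list(c(20, 60), c(21, 59), c(40), numeric(0), c(20, 60, 90))
  sm <- summarize_detections(det, cps = c(20, 60), T_len = 100, M = 3)
  # realizations 3 (displaced) and 5 (extra at 90) contain false discoveries
  expect_equal(sm$type1_rate, 40)
  # realizations 3 and 4 miss at least one true CP
  expect_equal(sm$type2_rate, 40)
  expect_equal(unname(sm$hit_rate["c20"]), 60)
  expect_equal(unname(sm$accuracy["c20"]), 60 - 40 / 3)
  expect_equal(sm$n_detected, c(2L, 2L, 1L, 0L, 3L))
})
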