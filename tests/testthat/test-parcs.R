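test_that("fixed-knot least squares agrees with an lm oracle", {
  set.seed(10)
  for (i in 1:10) {
    T_len <- sample(30:80, 1)
    y <- cumsum(rnorm(T_len))
    knots <- sort(sample(2:(T_len - 1), sample(1:4, 1)))
    fit <- parcs:::parcs_ols(matrix(y), knots)
    orc <- oracle_ols(y, knots)
    expect_equal(fit$fitted[, 1], orc$fitted, tolerance = 1e-8)
    expect_equal(fit$mse, orc$mse, tolerance = 1e-8)
    # bend coefficients match the oracle's truncated-power coefficients
    expect_equal(unname(fit$bend[, 1]),
                 unname(orc$coef[paste0("b", knots)]), tolerance = 1e-6)
  }
})

test_that("intercept-only fit returns the mean and population variance", {
  set.seed(11)
  y <- rnorm(50)
  fit <- parcs:::parcs_ols(matrix(y), integer(0))
  expect_equal(unname(fit$coefficients[1, 1]), mean(y))
  expect_equal(fit$mse, mean((y - mean(y))^2))
})

test_that("the paired hinge splines have the stated structure", {
  kp <- parcs:::knot_pair(50, 17)
  expect_true(all(kp$h_plus * kp$h_minus == 0))
  expect_equal(kp$h_plus + kp$h_minus, abs(seq_len(50) - 17))
})

test_that("a correct knot interpolates a noiseless step curve exactly", {
  y <- cusum_transform(noiseless_series(100, 20, 1))$y
  expect_lt(parcs:::parcs_ols(y, 20L)$mse, 1e-20)
})

test_that("adding a knot never increases the mse", {
  set.seed(12)
  for (i in 1:10) {
    y <- matrix(cumsum(rnorm(60)))
    knots <- sort(sample(2:59, 3))
    extra <- setdiff(sample(2:59, 5), knots)[1]
    expect_lte(parcs:::parcs_mse(y, c(knots, extra)),
               parcs:::parcs_mse(y, knots) + 1e-12)
  }
})

test_that("duplicate knots raise a rank error", {
  y <- matrix(cumsum(rnorm(40)))
  expect_error(parcs:::parcs_ols(y, c(10L, 10L)), "rank")
  expect_error(parcs(rnorm(40), knots = c(10, 10)), "distinct")
  expect_error(parcs(rnorm(40), knots = 1), "2:")
})

test_that("forward selection with L = 1 equals the exhaustive oracle", {
  set.seed(13)
  for (i in 1:8) {
    T_len <- sample(20:60, 1)
    x <- rnorm(T_len) + (runif(1) < 0.5) * (seq_len(T_len) > T_len / 2)
    y <- cusum_transform(x)$y
    fw <- parcs:::parcs_forward(y, 1L)
    expect_identical(fw$knots[1], oracle_best_knot(y[, 1]))
  }
})

test_that("over-selection plus pruning recovers noiseless multi-step knots", {
  # the greedy forward sweep compromises its first knot between two true
  # steps, which is why the forward bound L exceeds M: with L = 3M the true
  # knots enter the model and pruning removes the early compromises
  x <- noiseless_series(100, c(20, 60), c(2, -1))
  y <- cusum_transform(x)$y
  fw6 <- parcs:::parcs_forward(y, 6L)
  expect_true(all(c(20, 60) %in% fw6$knots))
  expect_setequal(parcs:::parcs_prune(y, fw6$knots, 2L), c(20, 60))
  expect_true(all(diff(fw6$mse_path) < 1e-12)) # monotone forward path
  # pruned fit agrees with the exhaustive two-knot oracle on a short series
  xs <- noiseless_series(30, c(8, 20), c(1.5, -1))
  ys <- cusum_transform(xs)$y
  fit <- parcs(xs, M = 2, L = 6)
  expect_identical(sort(fit$knots), oracle_best_pair(ys[, 1]))
  expect_lt(fit$mse, 1e-16)
})

test_that("pruning is the identity at L = M and reaches the null model", {
  y <- cusum_transform(rnorm(50))$y
  ks <- c(10L, 30L, 40L)
  expect_identical(parcs:::parcs_prune(y, ks, 3L), ks)
  expect_identical(parcs:::parcs_prune(y, ks, 0L), integer(0))
  expect_error(parcs:::parcs_prune(y, ks, 4L), "prune")
})

test_that("ranking orders knots by explained variance without changing the set", {
  x <- noiseless_series(100, c(20, 60), c(1, 2))
  fit <- parcs(x, M = 2, L = 6)
  expect_identical(fit$knots, c(60L, 20L))  # larger step ranked first
  expect_setequal(fit$knots, c(20L, 60L))
  f1 <- parcs(rnorm(40), M = 1, L = 3)
  expect_length(f1$knots, 1L)
})

test_that("noiseless fits recover change points and weights exactly", {
  set.seed(14)
  for (i in 1:10) {
    T_len <- sample(60:120, 1)
    M <- sample(1:3, 1)
    cps <- sort(sample(seq(10, T_len - 10, by = 8), M))
    w <- sample(c(-3, -2, -1, 1, 2, 3), M)
    x <- noiseless_series(T_len, cps, w, baseline = rnorm(1))
    fit <- parcs(x, M = M, L = 3 * M)
    expect_setequal(fit$knots, cps)
    expect_lt(fit$mse, 1e-16)
    st <- step_estimates(fit)
    ord <- match(cps, st$knots)
    expect_equal(unname(st$w[ord, 1]), w, tolerance = 1e-8)
  }
})

test_that("step inversion returns exact baseline and weights on noiseless input", {
  x <- noiseless_series(100, 20, 1)
  fit <- parcs(x, M = 1)
  st <- step_estimates(fit)
  expect_equal(unname(st$w[1, 1]), 1, tolerance = 1e-8)
  expect_equal(unname(st$b[1]), 0, tolerance = 1e-8)
  # null model reconstructs the constant mean
  f0 <- parcs(rnorm(50) + 3, M = 0)
  expect_equal(step_estimates(f0)$mean[, 1], rep(mean(f0$x), 50),
               tolerance = 1e-10)
})

test_that("a knot on a purely linear curve has zero bend", {
  y <- matrix(0.5 + 1.3 * seq_len(60))
  fit <- parcs:::parcs_ols(y, 25L)
  expect_lt(abs(fit$bend[1, 1]), 1e-10)
})

test_that("single-column matrix input equals vector input", {
  set.seed(15)
  x <- rnorm(70) + 2 * (seq_len(70) > 30)
  f1 <- parcs(x, M = 1)
  f2 <- parcs(matrix(x, ncol = 1), M = 1)
  expect_identical(f1$knots, f2$knots)
  expect_equal(f1$coefficients, f2$coefficients)
})

test_that("multivariate selection uses the response-averaged criterion", {
  x <- noiseless_series(80, c(25, 50), rbind(c(1, 0.5), c(-1, 2)), N = 2)
  fit <- parcs(x, M = 2, L = 4)
  expect_setequal(fit$knots, c(25, 50))
  expect_identical(dim(fit$bend), c(2L, 2L))
  expect_lt(fit$mse, 1e-16)
})

test_that("parcs model methods are coherent", {
  set.seed(16)
  spec <- step_model_spec(100, cps = c(20, 60), weights = c(2, -1),
                          sigma = 0.4, seed = 6)
  x <- simulate_step_series(spec)
  fit <- parcs(x, M = 2)
  expect_s3_class(fit, "parcs")
  expect_output(print(fit), "PARCS_2")
  expect_output(print(summary(fit)), "Ranked candidates")
  expect_identical(dim(coef(fit)), c(4L, 1L))           # 1, t, 2 bends
  expect_identical(dim(coef(fit, "steps")), c(2L, 1L))
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_equal(predict(fit, "cusum"), fitted(fit))
  rs <- residuals(fit, "series")
  expect_equal(rs + predict(fit, "mean"), fit$x)
  sims <- simulate(fit, nsim = 2, seed = 1, k = 2)
  expect_length(sims, 2L)
  expect_identical(dim(sims[[1]]), dim(x))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
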