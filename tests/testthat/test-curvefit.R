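test_that("sigmoid evaluation matches closed forms", {
  p <- list(P = 0, M = 10, L = 0, K = 5, Q = 1)
  expect_equal(sigmoid_eval(p, 5), 5)
  expect_lte(sigmoid_eval(p, 5 - 40), 1e-12)
  expect_equal(sigmoid_eval(p, 5 + 40), 10, tolerance = 1e-12)
  p8 <- list(P = 0, M = 8, L = 0, K = 0, Q = 1)
  expect_equal(sigmoid_eval(p8, log(3)), 6) # 8 / (1 + 1/3)
  expect_error(sigmoid_eval(list(P = 0, M = 1, L = 0, K = 0, Q = -1), 0), "Q must be positive")
})

test_that("sigmoid is monotone between its asymptotes", {
  set.seed(61)
  for (rep in 1:20) {
    p <- list(
      P = runif(1, -1, 1), M = runif(1, 1.5, 6), L = runif(1, -1, 1),
      K = runif(1, 0, 10), Q = runif(1, 0.1, 3)
    )
    x <- seq(-20, 30, length.out = 400)
    y <- sigmoid_eval(p, x)
    expect_true(all(diff(y) >= 0))
    expect_true(all(y >= p$P - 1e-9 & y <= p$M + 1e-9))
  }
})

test_that("inversion is the exact inverse of evaluation", {
  p8 <- list(P = 0, M = 8, L = 0, K = 0, Q = 1)
  expect_equal(invert_sigmoid(p8, 6), log(3))
  expect_error(invert_sigmoid(p8, 0), class = "mepkit_out_of_range")
  expect_error(invert_sigmoid(p8, 8), class = "mepkit_out_of_range")

  set.seed(67)
  for (rep in 1:100) {
    p <- list(
      P = runif(1, -1, 1), M = runif(1, 1.5, 6), L = runif(1, -1, 1),
      K = runif(1, 0, 10), Q = runif(1, 0.1, 3)
    )
    y <- runif(1, p$P + 1e-3, p$M - 1e-3)
    expect_equal(sigmoid_eval(p, invert_sigmoid(p, y)), y, tolerance = 1e-9)
  }
})

test_that("initial estimates follow the percentile-window conventions", {
  est <- initial_estimates(1:20, 1:20)
  expect_equal(est$P, 3) # median of sorted y[1..5]
  expect_equal(est$M, 18.5) # median of sorted y[17..20]
  expect_equal(est$K, 10.5) # mean of the two x whose y are nearest 10.75
  expect_false(est$degenerate)

  # exactly sigmoidal data: K0 within one intensity step of the half-max point
  p <- list(P = 0.1, M = 2, L = 0, K = 5, Q = 1)
  est2 <- initial_estimates(1:9, sigmoid_eval(p, 1:9))
  expect_lte(abs(est2$K - 5), 1)

  est3 <- initial_estimates(1:10, rep(2, 10))
  expect_true(est3$degenerate)
  expect_equal(est3$P, 2)

  expect_error(initial_estimates(1:3, 1:3), "at least 4")
})

test_that("noise-free fits recover the generating parameters", {
  x <- 1:9
  truth <- list(P = 0.1, M = 2, L = 0, K = 5, Q = 1)
  fit <- fit_recruitment(x, sigmoid_eval(truth, x), warn = FALSE)
  expect_lt(abs(fit$params$P - truth$P) / truth$M, 0.02)
  expect_lt(abs(fit$params$M - truth$M) / truth$M, 0.02)
  expect_lt(abs(fit$midpoint - sigmoid_midpoint(truth)) / sigmoid_midpoint(truth), 0.02)
  expect_lt(fit$fit_error, 0.1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  # dense curve spans the data and matches the parameters exactly
  expect_equal(range(fit$x_dense), range(x))
  expect_identical(fit$y_dense, sigmoid_eval(fit$params, fit$x_dense))
})

test_that("stopping-rule precedence: a loose tolerance returns the initial estimates", {
  x <- 1:9
  y <- sigmoid_eval(list(P = 0.1, M = 2, L = 0, K = 5, Q = 1), x)
  fit <- fit_recruitment(x, y, tolerance = 1e9, warn = FALSE)
  expect_equal(fit$stop_rule, "tolerance")
  expect_equal(fit$iterations, 0L)
  est <- initial_estimates(x, y)
  expect_equal(fit$params$P, est$P)
  expect_equal(fit$params$M, est$M)
  expect_equal(fit$params$K, est$K)
})

test_that("a flat objective halts by the stall rule without looping forever", {
  fit <- fit_recruitment(1:6, rep(1, 6), tolerance = 0, stall_delta = 0, warn = FALSE)
  expect_equal(fit$stop_rule, "stall")
  expect_equal(fit$stall_count, 10L)
  expect_equal(fit$iterations, 10L)
  expect_equal(fit$fit_error, 0)

  # flat data under defaults: degenerate init already satisfies the tolerance
  fit2 <- fit_recruitment(1:6, rep(1, 6), warn = FALSE)
  expect_equal(fit2$stop_rule, "tolerance")
  expect_true(fit2$degenerate)
  expect_equal(sigmoid_eval(fit2$params, 3.5), 1)
})

test_that("the fit error is invariant to rescaling the response", {
  set.seed(71)
  x <- 1:9
  y <- sigmoid_eval(list(P = 0.1, M = 2, L = 0.3, K = 5, Q = 1), x) * (1 + rnorm(9, 0, 0.08))
  f1 <- fit_recruitment(x, y, warn = FALSE)
  f2 <- fit_recruitment(x, 1000 * y, warn = FALSE)
  expect_equal(f1$fit_error, f2$fit_error, tolerance = 1e-6)
  expect_equal(f2$params$M / f1$params$M, 1000, tolerance = 1e-3)
})

test_that("r_squared matches hand computations and handles degenerate data", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5) # 1 - 1/2
  expect_equal(r_squared(rep(2, 4), rep(2, 4)), 1)
  expect_true(is.na(r_squared(rep(2, 4), c(2, 2, 2, 3))))
  expect_error(r_squared(1:3, 1:4), "same length")
  set.seed(73)
  for (rep in 1:20) {
    yy <- rnorm(10)
    yh <- yy + rnorm(10, 0, 0.5)
    expect_lte(r_squared(yy, yh), 1)
  }
})

test_that("saturation uses a strict 0.2 bound on the normalized last-three slope", {
  # collinear construction: last three normalized points with slope h
  sat_probe <- function(h) {
    y <- c(0.05, 0.1, 1 - 2 * h, 1 - h, 1)
    saturation_check(1:5, y, warn = FALSE)
  }
  r <- sat_probe(0.1)
  expect_true(r$saturated)
  expect_equal(r$slope, 0.1, tolerance = 1e-9)
  expect_false(sat_probe(0.5)$saturated)
  expect_warning(
    saturation_check(1:5, c(0.05, 0.1, 0, 0.5, 1)),
    class = "mepkit_no_saturation"
  )
  # boundary: slope not strictly below 0.2 means not saturated
  b <- sat_probe(0.2)
  expect_gte(b$slope, 0.2)
  expect_false(b$saturated)
  expect_error(saturation_check(1:2, 1:2), "at least 3")

  # normalization makes the bound dimensionless: rescaling y or x changes nothing
  y <- c(0.05, 0.1, 0.55, 0.8, 1)
  a <- saturation_check(1:5, y, warn = FALSE)
  b2 <- saturation_check((1:5) * 0.5, y * 37, warn = FALSE)
  expect_equal(a$slope, b2$slope, tolerance = 1e-12)
})

test_that("recovery from noisy means is accurate in the median over many curves", {
  set.seed(79)
  n_curves <- 60
  err_m <- err_k <- numeric(n_curves)
  for (i in seq_len(n_curves)) {
    truth <- list(
      P = runif(1, 0, 0.5), M = runif(1, 1, 4), L = runif(1, -0.5, 0.5),
      K = runif(1, 3, 7), Q = 1
    )
    x <- 1:10
    y <- sigmoid_eval(truth, x) * (1 + rnorm(10, 0, 0.05))
    fit <- fit_recruitment(x, y, warn = FALSE)
    err_m[i] <- abs(fit$params$M - truth$M) / truth$M
    err_k[i] <- abs(fit$midpoint - truth$K) / truth$K
  }
  expect_lte(median(err_m), 0.05)
  expect_lte(median(err_k), 0.05)
})

test_that("tidy and glance summarize a fit", {
  x <- 1:9
  fit <- fit_recruitment(x, sigmoid_eval(list(P = 0, M = 2, L = 0, K = 5, Q = 1), x),
    warn = FALSE
  )
  td <- tidy(fit)
  expect_equal(td$term, c("P", "M", "L", "K", "Q"))
  expect_true(td$fixed[td$term == "Q"])
  gl <- glance(fit)
  expect_equal(gl$n, 9)
  expect_s3_class(autoplot(fit), "ggplot")
})
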