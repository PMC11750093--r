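test_that("the lag grid follows the half-open convention", {
  g <- make_lag_grid(-0.1, 1.0, 100)
  expect_equal(g$K, 110L)
  expect_equal(g$tau[1], -0.1)
  expect_equal(g$tau[g$K], 1.0 - 1 / 100)
  expect_equal(make_lag_grid(0, 0.5, 100)$K, 50L)
  expect_equal(make_lag_grid(-0.1, 1.0, 200)$K, 220L)
  expect_error(make_lag_grid(0.5, 0.1, 100), "exceed")
})

test_that("predict_response is the lagged convolution sum", {
  g <- make_lag_grid(0, 0.2, 100)  # K = 20
  beta <- matrix(sin(seq(0, pi, length.out = g$K)), 1)
  attr(beta, "grid") <- g
  x <- numeric(300); x[51] <- 1    # unit impulse at t0 = sample 51
  yhat <- predict_response(beta, matrix(x, 1), grid = g)
  expect_equal(yhat[51:70], as.numeric(beta))
  expect_equal(sum(abs(yhat[-(51:70)])), 0)

  expect_equal(max(abs(predict_response(matrix(0, 1, g$K), matrix(x, 1),
                                        grid = g))), 0)

  # superposition in predictors and linearity in kernels
  set.seed(41)
  x2 <- rbind(rnorm(300), rnorm(300))
  b2 <- rbind(rnorm(g$K), rnorm(g$K))
  y_joint <- predict_response(b2, x2, grid = g)
  y_sep <- predict_response(b2[1, , drop = FALSE], x2[1, , drop = FALSE],
                            grid = g) +
           predict_response(b2[2, , drop = FALSE], x2[2, , drop = FALSE],
                            grid = g)
  expect_equal(y_joint, y_sep)
  expect_equal(predict_response(2 * b2, x2, grid = g), 2 * y_joint)
})

test_that("reconstruction accuracy is the coefficient of determination", {
  set.seed(42)
  y <- rnorm(200)
  expect_equal(reconstruction_accuracy(y, y), 1)
  expect_equal(reconstruction_accuracy(y, rep(mean(y), 200)), 0)
  y0 <- y - mean(y)
  expect_equal(reconstruction_accuracy(y0, -y0), -3)
  expect_error(reconstruction_accuracy(rep(1, 10), rnorm(10)), "constant")
})

test_that("boosting recovers a known kernel and suppresses a null predictor", {
  set.seed(43)
  sr <- 50; dur <- 100; Tn <- sr * dur
  g <- make_lag_grid(-0.1, 0.5, sr)
  on <- sort(runif(250, 0, dur - 1))
  x_sig <- impulse_series(on, rnorm(250) + 2, sr, dur, "signal")
  on2 <- sort(runif(250, 0, dur - 1))
  x_null <- impulse_series(on2, rnorm(250) + 2, sr, dur, "null")
  kern <- gauss_kernel(g, peak = 0.15, width = 0.07)
  xm <- normalize_series(rbind(signal = x_sig$values, null = x_null$values))
  y_clean <- predict_response(matrix(kern, 1), xm[1, , drop = FALSE],
                              grid = g)
  y <- normalize_series(y_clean)
  idx <- seq_len(Tn)
  fit <- boost_fit(xm, y, train = idx[idx <= 0.7 * Tn],
                   validation = idx[idx > 0.7 * Tn], grid = g,
                   sample_rate = sr)
  expect_gte(cor(fit$kernel["signal", ], kern), 0.95)
  l1 <- rowSums(abs(fit$kernel))
  expect_lte(l1["null"], 0.05 * l1["signal"])

  expect_error(boost_fit(xm, rep(1, Tn), idx[1:10], idx[11:20], g,
                         sample_rate = sr), "constant")
})

test_that("cross-validation bookkeeping rotates segments as specified", {
  set.seed(44)
  sr <- 50; dur <- 40
  on <- sort(runif(100, 0, dur - 1))
  x <- impulse_series(on, rnorm(100) + 1, sr, dur)
  g <- make_lag_grid(-0.1, 0.3, sr)
  kern <- gauss_kernel(g)
  sim <- simulate_responses(x, simulation_spec(
    n_subjects = 1, n_channels = 1, kernels = list(kern), grid = g,
    snr = 4), seed = 44)
  fit <- trf(x, sim$responses[[1]], tmin = -0.1, tmax = 0.3, max_iter = 500)
  runs <- fit$folds$runs
  expect_equal(nrow(runs), 20)                     # 5 folds x 4 rotations
  expect_equal(as.integer(table(runs$test)), rep(4L, 5))
  expect_equal(as.integer(table(runs$validation)), rep(4L, 5))
  for (i in 1:5) {
    sub <- runs[runs$test == i, ]
    expect_setequal(sub$validation, setdiff(1:5, i))
    expect_false(any(grepl(as.character(i), sub$train)))
  }
})

test_that("held-out accuracy approaches the noise ceiling and is null for noise", {
  set.seed(45)
  sr <- 50; dur <- 120; snr <- 6
  on <- sort(runif(320, 0, dur - 1))
  x <- impulse_series(on, rnorm(320) + 2, sr, dur)
  g <- make_lag_grid(-0.1, 0.5, sr)
  kern <- gauss_kernel(g, peak = 0.18, width = 0.09)
  sim <- simulate_responses(x, simulation_spec(
    n_subjects = 1, n_channels = 3, kernels = list(kern), grid = g,
    snr = snr), seed = 45)
  fit <- trf(x, sim$responses[[1]], tmin = -0.1, tmax = 0.5)
  ceiling_r2 <- snr / (1 + snr)  # var(signal) / var(signal + noise)
  expect_lt(abs(mean(fit$accuracy) - ceiling_r2), 0.1 * ceiling_r2)

  noise <- matrix(rnorm(3 * sr * dur), 3)
  fit0 <- trf(x, noise, sample_rate = sr, tmin = -0.1, tmax = 0.5)
  expect_lte(mean(fit0$accuracy), 0.01)
})

test_that("trf objects expose the standard modelling methods", {
  set.seed(46)
  sr <- 50; dur <- 60
  on <- sort(runif(150, 0, dur - 1))
  x <- impulse_series(on, rnorm(150) + 1, sr, dur, "nc")
  g <- make_lag_grid(-0.1, 0.4, sr)
  sim <- simulate_responses(x, simulation_spec(
    n_subjects = 1, n_channels = 2, kernels = list(gauss_kernel(g)),
    grid = g, snr = 4), seed = 46)
  fit <- trf(x, sim$responses[[1]], tmin = -0.1, tmax = 0.4, max_iter = 800)

  expect_output(print(fit), "Boosted mTRF")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.trf")
  expect_output(print(sm), "Reconstruction accuracy")

  k <- coef(fit)
  expect_equal(dim(k), c(1, g$K, 2))
  k1 <- coef(fit, channel = 1)
  expect_equal(dim(k1), c(1L, g$K))

  ft <- fitted(fit)
  rs <- residuals(fit)
  expect_equal(dim(ft), dim(fit$y))
  expect_equal(ft + rs, fit$y)

  # prediction from the fitted kernels correlates with the fitted values
  pr <- predict(fit, newdata = x)
  expect_equal(dim(pr), dim(ft))
  expect_gt(cor(pr[1, ], ft[1, ]), 0.95)

  pdf(NULL)
  expect_silent(plot(fit, channel = 1))
  dev.off()

  expect_error(trf(x, sim$responses[[1]][, 1:100], tmin = -0.1, tmax = 0.4),
               "same samples")
  expect_error(trf(x, sim$responses[[1]][, 1:300, drop = FALSE][, 1:300],
                   tmin = -0.1, tmax = 0.4), "same samples")
})

test_that("trf refuses series too short for the fold scheme", {
  set.seed(47)
  x <- impulse_series(c(0.1, 0.5), c(1, 1), 50, 2)
  y <- rnorm(100)
  expect_error(trf(x, y, tmin = -0.1, tmax = 1.0), "at least folds")
})
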