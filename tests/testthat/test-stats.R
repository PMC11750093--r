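test_that("VIF is the diagonal of the inverse correlation matrix", {
  expect_equal(unname(vif(diag(4))), rep(1, 4))

  r <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(unname(vif(r)), rep(1 / (1 - 0.64), 2), tolerance = 1e-12)

  # regression oracle: VIF_i = 1 / (1 - R^2 of predictor i on the rest)
  set.seed(51)
  x <- matrix(rnorm(400 * 5), 400, 5)
  x[, 2] <- 0.7 * x[, 1] + 0.3 * x[, 2]
  x[, 5] <- 0.5 * x[, 3] - 0.4 * x[, 4] + 0.6 * x[, 5]
  r5 <- cor(x)
  v <- vif(r5)
  for (i in 1:5) {
    fit <- lm(x[, i] ~ x[, -i])
    r2 <- summary(fit)$r.squared
    expect_equal(unname(v[i]), 1 / (1 - r2), tolerance = 1e-8)
  }
  expect_true(all(v >= 1))

  # exactly collinear set is refused with a diagnostic
  xs <- cbind(a = x[, 1], b = x[, 2], c = x[, 1] + x[, 2])
  expect_error(vif(cov2cor(crossprod(scale(xs)))), "collinear")
})

test_that("VIF equals 1 exactly when a predictor is orthogonal to the rest", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.6   # predictor 3 orthogonal
  v <- vif(r)
  expect_equal(unname(v[3]), 1, tolerance = 1e-12)
  expect_gt(v[1], 1)
})

test_that("graph smoothing preserves the spatial mean", {
  g <- lattice_graph(6, 5)
  set.seed(52)
  x <- matrix(rnorm(4 * 30), 4, 30)
  sx <- graph_smooth(x, g, sd = 1.5)
  expect_equal(rowMeans(sx), rowMeans(x), tolerance = 1e-12)
  # smoothing shrinks spatial roughness
  rough <- function(m) mean(apply(m, 1, sd))
  expect_lt(rough(sx), rough(x))
  expect_equal(graph_smooth(x, g, sd = 0), x)
})

test_that("accuracy contrasts difference the smoothed maps", {
  g <- lattice_graph(5, 4)
  set.seed(53)
  a <- matrix(rnorm(60), 3, 20)
  expect_equal(accuracy_contrast(a, a, g), matrix(0, 3, 20),
               tolerance = 1e-12)
  d <- accuracy_contrast(a + 0.25, a, g)
  expect_equal(d, matrix(0.25, 3, 20), tolerance = 1e-10)
  expect_error(accuracy_contrast(a, a[, 1:10]), "shape")
})

test_that("spatial cluster permutation finds planted effects and nothing in zeros", {
  g <- lattice_graph(8, 8)
  zero <- matrix(0, 12, 64)
  res0 <- cluster_perm_spatial(zero + 1e-15 * rnorm(length(zero)), g,
                               n_perm = 100, seed = 1)
  expect_equal(nrow(res0$table), 0)

  set.seed(54)
  patch <- as.vector(outer(2:4, (1:5 - 1) * 8, "+"))  # 15-channel block
  x <- matrix(rnorm(24 * 64), 24, 64)
  x[, patch] <- x[, patch] + 1.5
  res <- cluster_perm_spatial(x, g, min_channels = 10, n_perm = 500,
                              seed = 2)
  expect_gt(nrow(res$table), 0)
  top <- which.max(res$table$n_points)
  expect_true(all(patch %in% res$members[[top]]))
  expect_lt(res$table$p[top], 0.01)
  # t_av x member count equals the cluster statistic exactly
  expect_equal(res$table$t_av * res$table$n_points, res$table$t_sum)
})

test_that("spatiotemporal clusters respect channel and time extent minima", {
  g <- lattice_graph(4, 4)
  S <- 14; C <- 16; L <- 25; sr <- 50
  zeros <- array(rnorm(S * C * L, sd = 1e-12), c(S, C, L))
  r0 <- cluster_perm_spatiotemporal(zeros, g, sr, min_channels = 4,
                                    min_time = 0.08, n_perm = 100, seed = 3)
  expect_equal(nrow(r0$table), 0)

  set.seed(55)
  x <- array(rnorm(S * C * L, sd = 1), c(S, C, L))
  chans <- c(6, 7, 10, 11)          # 2x2 interior patch
  lags <- 8:17                      # 200 ms at 50 Hz
  x[, chans, lags] <- x[, chans, lags] + 1.6
  res <- cluster_perm_spatiotemporal(x, g, sr, min_channels = 4,
                                     min_time = 0.08, n_perm = 300,
                                     seed = 4)
  expect_gt(nrow(res$table), 0)
  top <- which.max(res$table$n_points)
  expect_lt(res$table$p[top], 0.05)
  expect_gte(res$table$n_channels[top], 4)
  expect_gte(res$table$lag_span[top], round(0.08 * sr))

  # too-short planted window is filtered out by the time minimum
  y <- array(rnorm(S * C * L, sd = 1e-12), c(S, C, L))
  y[, chans, 10] <- y[, chans, 10] + 5
  ry <- cluster_perm_spatiotemporal(y, g, sr, min_channels = 4,
                                    min_time = 0.08, n_perm = 100, seed = 5)
  expect_equal(nrow(ry$table), 0)
})

test_that("permutation p-values are invariant to channel relabeling", {
  set.seed(56)
  S <- 10; C <- 12
  g <- lattice_graph(12, 1)
  x <- array(rnorm(S * C * 10), c(S, C, 10))
  x[, 4:9, 3:8] <- x[, 4:9, 3:8] + 1.4
  perm <- rev(seq_len(C))            # relabel channels consistently
  g2 <- channel_graph(C, cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]))
  x2 <- x[, order(perm), , drop = FALSE]
  r1 <- cluster_perm_spatiotemporal(x, g, 50, min_channels = 3,
                                    min_time = 0.06, n_perm = 200, seed = 7)
  r2 <- cluster_perm_spatiotemporal(x2, g2, 50, min_channels = 3,
                                    min_time = 0.06, n_perm = 200, seed = 7)
  expect_equal(sort(r1$table$t_sum), sort(r2$table$t_sum), tolerance = 1e-10)
  expect_equal(sort(r1$table$p), sort(r2$table$p))
})

test_that("baseline correction rectifies and re-references to negative lags", {
  g <- make_lag_grid(-0.1, 0.4, 50)
  const <- matrix(0.7, 3, g$K)
  expect_equal(baseline_correct(const, g), matrix(0, 3, g$K))

  set.seed(57)
  k <- matrix(abs(rnorm(3 * g$K)), 3, g$K)
  k[, g$tau < 0] <- 0
  expect_equal(baseline_correct(k, g), abs(k))

  kc <- baseline_correct(matrix(rnorm(3 * g$K), 3, g$K), g)
  expect_equal(rowMeans(kc[, g$tau < 0]), rep(0, 3), tolerance = 1e-12)

  g0 <- make_lag_grid(0, 0.4, 50)
  expect_error(baseline_correct(const, g0), "no negative lags")
})

test_that("Bonferroni alphas match the reported corrections", {
  expect_equal(round(bonferroni_alpha(6), 4), 0.0083)
  expect_equal(round(bonferroni_alpha(9), 4), 0.0056)
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_error(bonferroni_alpha(0))
})

test_that("ROI summaries are plain masked means", {
  set.seed(58)
  m <- matrix(rnorm(5 * 20), 5, 20)
  expect_equal(roi_summary(m, 7), m[, 7])
  u <- matrix(2.5, 5, 20)
  expect_equal(roi_summary(u, c(3, 9, 14)), rep(2.5, 5))
  mask <- c(2, 5, 11, 19)
  expect_equal(roi_summary(m, mask), rowMeans(m[, mask]))

  a <- array(rnorm(5 * 20 * 7), c(5, 20, 7))
  got <- roi_summary(a, mask)
  brute <- apply(a[, mask, ], c(1, 3), mean)
  expect_equal(got, brute)
  expect_error(roi_summary(m, integer(0)), "empty")
})

test_that("cluster tables round-trip through the tab-delimited writer", {
  set.seed(59)
  g <- lattice_graph(6, 4)
  x <- matrix(rnorm(20 * 24), 20, 24)
  x[, 1:12] <- x[, 1:12] + 1.2
  res <- cluster_perm_spatial(x, g, min_channels = 5, n_perm = 100, seed = 9)
  path <- tempfile()
  write_cluster_table(res, path)
  back <- read.delim(path)
  expect_equal(back$t_sum, res$table$t_sum)
  unlink(path)
})

test_that("channel graphs validate edges and read from edge lists", {
  expect_error(channel_graph(3, rbind(c(1, 1))), "self-loops")
  expect_error(channel_graph(3, rbind(c(1, 4))), "out of range")
  g <- channel_graph(4, rbind(c(1, 2), c(2, 1), c(3, 4)))
  expect_equal(nrow(g$edges), 2)  # duplicates collapse
  path <- tempfile()
  writeLines(c("# edges", "1 2", "2 3"), path)
  gr <- read_channel_graph(path, 4)
  expect_equal(gr$n, 4)
  expect_equal(nrow(gr$edges), 2)
  unlink(path)
})
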