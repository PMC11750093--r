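test_that("tree generation is seeded, well-formed and respects trace settings", {
  spec <- grammar_spec()
  t1 <- generate_trees(spec, 30, seed = 7)
  t2 <- generate_trees(spec, 30, seed = 7)
  expect_identical(lapply(t1, write_bracketed), lapply(t2, write_bracketed))
  for (tr in t1) {
    expect_s3_class(tr, "syntax_tree")
    # round-trips through the reader
    expect_identical(unclass(parse_bracketed(write_bracketed(tr))),
                     unclass(tr))
  }
  no_trace <- generate_trees(grammar_spec(trace_prob = 0), 50, seed = 8)
  expect_false(any(unlist(lapply(no_trace,
                                 function(t) tree_leaves(t)$is_trace))))
  some_trace <- generate_trees(grammar_spec(trace_prob = 0.6), 50, seed = 8)
  expect_true(any(unlist(lapply(some_trace,
                                function(t) tree_leaves(t)$is_trace))))
})

test_that("headedness reshapes the temporal distribution of closure load", {
  n <- 500
  mixed <- generate_trees(grammar_spec(head_final = c("VP", "IP"),
                                       trace_prob = 0), n, seed = 9)
  initial <- generate_trees(grammar_spec(head_final = character(0),
                                         trace_prob = 0), n, seed = 9)
  # in head-final (OV) clauses the verb closes its VP and the clause, so
  # verbs carry more bottom-up load than in head-initial (VO) clauses,
  # where the verb opens the VP instead
  verb_bu <- function(trees) {
    mean(unlist(lapply(trees, function(tr) {
      leaves <- tree_leaves(tr)
      b <- node_count_bottom_up(tr)
      b[grepl("^verb", leaves$token)]
    })))
  }
  expect_gt(verb_bu(mixed), verb_bu(initial))
  # conversely, head-initial grammars are right-branching, so their deep
  # right edge concentrates closure on the sentence-final word
  final_bu <- function(trees) {
    mean(vapply(trees, function(tr) {
      b <- fold_trace_counts(node_count_bottom_up(tr))
      b[length(b)]
    }, numeric(1)))
  }
  expect_gt(final_bu(initial), final_bu(mixed))
})

test_that("word timings are seeded, increasing, and delta-paced for demanding words", {
  spec <- grammar_spec()
  trees <- generate_trees(spec, 120, seed = 10)
  w1 <- generate_timings(trees, seed = 11)
  w2 <- generate_timings(trees, seed = 11)
  expect_identical(w1, w2)
  expect_true(all(diff(w1$onset) > 0))
  expect_true(all(w1$offset > w1$onset))

  tab <- node_count_table(trees, timings = w1)
  for (col in c("nc_topdown", "nc_bottomup", "nc_leftcorner")) {
    r <- syntactic_rate(tab$onset, tab[[col]])
    expect_gte(r$median, 0.5)
    expect_lte(r$median, 4)
  }
})

test_that("synthetic word statistics are normalized and Zipf-controlled", {
  voc <- sprintf("w%03d", 1:200)
  ws <- generate_word_statistics(voc, zipf_exponent = 1, seed = 12)
  expect_identical(ws, generate_word_statistics(voc, 1, seed = 12))
  expect_true(all(ws$per_million > 0 & ws$per_million <= 1))
  expect_true(all(ws$probability > 0 & ws$probability <= 1))
  nw <- attr(ws, "next_word")
  expect_equal(rowSums(nw), rep(1, 200), tolerance = 1e-9)

  ws2 <- generate_word_statistics(voc, zipf_exponent = 1.8, seed = 12)
  expect_gt(var(-log2(ws2$per_million)), var(-log2(ws$per_million)))
  expect_error(generate_word_statistics(character(0)), "empty")
})

test_that("1/f noise is band-limited, standardized and spectrally sloped", {
  set.seed(13)
  sr <- 100; n <- 2^14
  x <- noise_1f(n, sr, exponent = 1, band = c(0.5, 4))
  expect_equal(mean(x), 0, tolerance = 1e-10)
  expect_equal(sd(x), 1, tolerance = 1e-10)
  sp <- Mod(fft(x))[2:(n / 2)]^2
  f <- (1:(n / 2 - 1)) * sr / n
  in_band <- f >= 0.5 & f <= 4
  expect_gt(sum(sp[in_band]) / sum(sp), 0.99)
  # 1/f slope: lower in-band frequencies carry more power
  lo <- f >= 0.5 & f < 1.5; hi <- f > 2.5 & f <= 4
  expect_gt(mean(sp[lo]), mean(sp[hi]))
})

test_that("simulated responses follow the forward model at the requested SNR", {
  set.seed(14)
  sr <- 50; dur <- 60
  on <- sort(runif(150, 0, dur - 1))
  x <- impulse_series(on, rnorm(150) + 2, sr, dur, "nc")
  g <- make_lag_grid(-0.1, 0.4, sr)
  kern <- gauss_kernel(g)

  # noise-free limit reproduces predict_response exactly
  hi <- simulate_responses(x, simulation_spec(
    n_subjects = 1, n_channels = 1, kernels = list(kern), grid = g,
    snr = 1e12), seed = 15)
  direct <- predict_response(matrix(kern, 1), matrix(x$values, 1), grid = g)
  expect_equal(hi$responses[[1]][1, ], direct, tolerance = 1e-4)

  # realized SNR within 10% of requested
  sim <- simulate_responses(x, simulation_spec(
    n_subjects = 3, n_channels = 2, kernels = list(kern), grid = g,
    snr = 4), seed = 16)
  for (s in 1:3) {
    noise <- sim$responses[[s]] - sim$signal
    snr_hat <- apply(sim$signal, 1, var) / apply(noise, 1, var)
    expect_true(all(abs(snr_hat - 4) < 0.1 * 4))
  }

  # reproducibility
  sim2 <- simulate_responses(x, simulation_spec(
    n_subjects = 3, n_channels = 2, kernels = list(kern), grid = g,
    snr = 4), seed = 16)
  expect_identical(sim$responses, sim2$responses)
})

test_that("all-zero kernels produce untrackable pure noise", {
  set.seed(17)
  sr <- 50; dur <- 60
  on <- sort(runif(150, 0, dur - 1))
  x <- impulse_series(on, rnorm(150) + 2, sr, dur, "nc")
  g <- make_lag_grid(-0.1, 0.4, sr)
  sim <- simulate_responses(x, simulation_spec(
    n_subjects = 1, n_channels = 2, kernels = list(rep(0, g$K)), grid = g,
    snr = 4), seed = 18)
  expect_equal(max(abs(sim$signal)), 0)
  fit <- trf(x, sim$responses[[1]], tmin = -0.1, tmax = 0.4, max_iter = 2000)
  expect_lte(mean(fit$accuracy), 0.01)
})

test_that("node-count predictors reproduce a positively correlated regime", {
  spec <- grammar_spec()
  trees <- generate_trees(spec, 150, seed = 19)
  tim <- generate_timings(trees, seed = 20)
  tab <- node_count_table(trees, timings = tim)
  dur <- max(tab$offset) + 1
  sr <- 50
  mk <- function(col, nm) impulse_series(tab$onset, tab[[col]], sr, dur, nm)
  preds <- list(mk("nc_bottomup", "bu"), mk("nc_topdown", "td"),
                mk("nc_leftcorner", "lc"))
  cc <- predictor_collinearity(preds)
  expect_true(all(cc$correlation[upper.tri(cc$correlation)] > 0.3))
  expect_true(all(cc$vif >= 1))
})
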