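#' Grammar specification for synthetic treebanks
#'
#' Parameters of the X-bar-style random sentence generator. The default
#' headedness map makes VP and IP head-final (verb after its object, as in
#' Dutch clause structure) and all other phrases head-initial, which is the
#' structural property that differentiates the temporal profiles of the
#' three parsing strategies.
#'
#' @param head_final Character vector of head-final phrase categories.
#'   Default `c("VP", "IP")`.
#' @param branch_prob Probability that a verb takes a phrasal complement.
#'   Default 0.7.
#' @param embed_prob Probability of one further level of embedding (PP
#'   inside NP, adjunct on VP). Default 0.35.
#' @param det_prob Probability that an NP has a determiner. Default 0.7.
#' @param trace_prob Probability that a complement position is realized as
#'   a trace (empty element). Default 0.1.
#' @param max_depth Maximum recursion depth. Default 5.
#' @param vocabulary Named list of word strings per part of speech
#'   (`N`, `V`, `D`, `P`, `A`). A small pseudo-lexicon by default.
#' @return An object of class `grammar_spec`.
#' @export
grammar_spec <- function(head_final = c("VP", "IP"), branch_prob = 0.7,
                         embed_prob = 0.35, det_prob = 0.7,
                         trace_prob = 0.1, max_depth = 5,
                         vocabulary = NULL) {
  stopifnot(branch_prob >= 0, branch_prob <= 1, embed_prob >= 0,
            embed_prob <= 1, det_prob >= 0, det_prob <= 1,
            trace_prob >= 0, trace_prob <= 1)
  if (is.null(vocabulary))
    vocabulary <- list(
      N = sprintf("noun%02d", 1:40), V = sprintf("verb%02d", 1:25),
      D = c("de", "het", "een"), P = sprintf("prep%02d", 1:8),
      A = sprintf("adj%02d", 1:15))
  structure(list(head_final = head_final, branch_prob = branch_prob,
                 embed_prob = embed_prob, det_prob = det_prob,
                 trace_prob = trace_prob, max_depth = max_depth,
                 vocabulary = vocabulary),
            class = "grammar_spec")
}

#' Generate a random synthetic treebank
#'
#' Draws `n_sentences` well-formed trees from the grammar in `spec`:
#' clauses (IP) with an NP subject and a VP whose head is placed last when
#' VP is head-final; NPs optionally carry determiners, adjectives and PP
#' complements; complement positions become trace leaves with probability
#' `trace_prob`. Deterministic given `seed`.
#'
#' @param spec A [grammar_spec()].
#' @param n_sentences Number of trees.
#' @param seed RNG seed.
#' @return List of `syntax_tree` objects.
#' @export
generate_trees <- function(spec, n_sentences, seed = 1) {
  stopifnot(inherits(spec, "grammar_spec"))
  set.seed(seed)
  voc <- spec$vocabulary
  hf <- function(cat) cat %in% spec$head_final
  pre <- function(pos) syntax_tree(pos, terminal = sample(voc[[pos]], 1))
  trace_leaf <- function(cat) syntax_tree(cat, terminal = "t", trace = TRUE)

  gen_np <- function(depth) {
    n_part <- list(pre("N"))
    if (depth < spec$max_depth && stats::runif(1) < spec$embed_prob)
      n_part <- list(syntax_tree("N1", children = c(n_part,
                       list(gen_pp(depth + 1)))))
    if (stats::runif(1) < spec$embed_prob)
      n_part <- c(list(syntax_tree("AP", children = list(pre("A")))), n_part)
    if (stats::runif(1) < spec$det_prob)
      n_part <- c(list(syntax_tree("DP", children = list(pre("D")))), n_part)
    if (length(n_part) == 1L && !is.null(n_part[[1]]$terminal))
      syntax_tree("NP", children = n_part)
    else
      syntax_tree("NP", children = n_part)
  }
  gen_pp <- function(depth) {
    obj <- if (depth < spec$max_depth) gen_np(depth + 1) else
      syntax_tree("NP", children = list(pre("N")))
    syntax_tree("PP", children = list(pre("P"), obj))   # head-initial
  }
  gen_vp <- function(depth) {
    head <- pre("V")
    kids <- list(head)
    if (stats::runif(1) < spec$branch_prob) {
      comp <- if (stats::runif(1) < spec$trace_prob) trace_leaf("NP")
              else gen_np(depth + 1)
      kids <- if (hf("VP")) list(comp, head) else list(head, comp)
    }
    vp <- syntax_tree("VP", children = kids)
    if (depth < spec$max_depth && stats::runif(1) < spec$embed_prob) {
      adj <- gen_pp(depth + 1)
      vp <- syntax_tree("VP", children = if (hf("VP")) list(adj, vp)
                                         else list(vp, adj))
    }
    vp
  }
  gen_ip <- function() {
    ## the subject (specifier) precedes the verbal projection in both
    ## head-initial and head-final clauses; headedness varies VP-internal
    ## order only
    syntax_tree("IP", children = list(gen_np(1), gen_vp(1)))
  }
  lapply(seq_len(n_sentences), function(i) gen_ip())
}

#' Generate word timings for a treebank
#'
#' Log-normal word durations around `mean_word_dur`, with a short pause
#' between sentences; onsets are strictly increasing and traces get no
#' time. The defaults target naturalistic speech rates, under which the
#' inter-onset intervals of syntactically demanding words (node count > 2)
#' fall largely in the 0.5-4 Hz delta band.
#'
#' @param trees List of `syntax_tree` objects.
#' @param mean_word_dur Mean word duration in seconds. Default 0.35.
#' @param jitter Log-scale SD of the duration distribution. Default 0.3.
#' @param pause Mean pause between sentences in seconds. Default 0.25.
#' @param seed RNG seed.
#' @return Data frame with `sentence`, `word`, `token`, `onset`, `offset`
#'   (one row per overt word).
#' @export
generate_timings <- function(trees, mean_word_dur = 0.35, jitter = 0.3,
                             pause = 0.25, seed = 1) {
  if (mean_word_dur <= 0) stop("durations must be positive")
  set.seed(seed)
  meanlog <- log(mean_word_dur) - jitter^2 / 2
  t_cur <- 0
  rows <- list()
  for (s in seq_along(trees)) {
    leaves <- tree_leaves(trees[[s]])
    toks <- leaves$token[!leaves$is_trace]
    dur <- stats::rlnorm(length(toks), meanlog, jitter)
    onset <- t_cur + c(0, cumsum(dur[-length(dur)]))
    rows[[s]] <- data.frame(sentence = s, word = seq_along(toks),
                            token = toks, onset = onset,
                            offset = onset + dur,
                            stringsAsFactors = FALSE)
    t_cur <- onset[length(onset)] + dur[length(dur)] +
      stats::rexp(1, 1 / pause)
  }
  do.call(rbind, rows)
}

#' Generate synthetic word statistics
#'
#' Zipfian per-million frequencies (on the 0-1 scale), in-context
#' probabilities, and normalized next-word distributions for a vocabulary.
#'
#' @param vocabulary Character vector of word types.
#' @param zipf_exponent Zipf exponent of the frequency distribution.
#'   Default 1.
#' @param n_candidates Size of each next-word candidate set. Default
#'   `min(50, length(vocabulary))`.
#' @param seed RNG seed.
#' @return Data frame with `token`, `per_million`, `probability`; the
#'   matrix of next-word distributions (rows sum to 1) is attached as
#'   attribute `next_word`.
#' @export
generate_word_statistics <- function(vocabulary, zipf_exponent = 1,
                                     n_candidates = NULL, seed = 1) {
  if (!length(vocabulary)) stop("empty vocabulary")
  set.seed(seed)
  V <- length(vocabulary)
  if (is.null(n_candidates)) n_candidates <- min(50L, V)
  rank <- sample(V)                       # random rank assignment
  raw <- rank^(-zipf_exponent)
  per_million <- 0.03 * raw / max(raw)    # most frequent word ~3e4 per 1e6
  probability <- stats::rbeta(V, 1.2, 6)
  probability <- pmin(pmax(probability, 1e-6), 1)
  nw <- matrix(0, V, n_candidates)
  for (i in seq_len(V)) {
    g <- stats::rgamma(n_candidates, shape = 0.5)
    nw[i, ] <- g / sum(g)
  }
  out <- data.frame(token = vocabulary, per_million = per_million,
                    probability = probability, stringsAsFactors = FALSE)
  attr(out, "next_word") <- nw
  out
}

#' Band-limited 1/f Gaussian noise
#'
#' Spectral synthesis: Gaussian Fourier coefficients with amplitude
#' proportional to `f^(-exponent/2)`, restricted to `band`, inverse
#' transformed and standardized to unit variance.
#'
#' @param n Number of samples.
#' @param sample_rate Sampling rate in Hz.
#' @param exponent Spectral exponent of the `1/f^exponent` power law.
#'   Default 1.
#' @param band Passband in Hz, `c(lo, hi)`. Default `c(0.5, 4)` (delta
#'   band).
#' @return Numeric vector of length `n`, mean 0, variance 1.
#' @export
noise_1f <- function(n, sample_rate, exponent = 1, band = c(0.5, 4)) {
  nf <- n %/% 2
  f <- seq_len(nf) * sample_rate / n
  amp <- f^(-exponent / 2)
  amp[f < band[1] | f > band[2]] <- 0
  re <- stats::rnorm(nf) * amp
  im <- stats::rnorm(nf) * amp
  spec <- complex(real = c(0, re), imaginary = c(0, im))
  full <- c(spec, Conj(rev(spec[2:(nf + 1)])))[1:n]
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate noise (empty passband?)")
  x / s
}

#' Simulation specification for synthetic responses
#'
#' @param n_subjects Number of simulated subjects. Default 12.
#' @param n_channels Number of response channels.
#' @param kernels List of per-predictor true kernels: numeric vectors on
#'   the lag grid (shared across channels) in predictor order.
#' @param grid The [make_lag_grid()] the kernels live on.
#' @param gains Channels-by-predictors gain matrix (spatial pattern of each
#'   predictor's response). Default: all 1.
#' @param snr Signal-to-noise variance ratio (> 0). Default 4.
#' @param noise_exponent Spectral exponent of the 1/f noise. Default 1.
#' @param band Noise passband in Hz. Default `c(0.5, 4)`.
#' @param amp_jitter Log-scale SD of per-subject amplitude scaling.
#'   Default 0 (identical subjects up to noise).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 12, n_channels, kernels, grid,
                            gains = NULL, snr = 4, noise_exponent = 1,
                            band = c(0.5, 4), amp_jitter = 0) {
  if (snr <= 0) stop("'snr' must be positive")
  for (k in kernels)
    if (length(k) != grid$K) stop("each kernel must have grid$K values")
  if (is.null(gains)) gains <- matrix(1, n_channels, length(kernels))
  stopifnot(nrow(gains) == n_channels, ncol(gains) == length(kernels))
  structure(list(n_subjects = n_subjects, n_channels = n_channels,
                 kernels = kernels, grid = grid, gains = gains, snr = snr,
                 noise_exponent = noise_exponent, band = band,
                 amp_jitter = amp_jitter),
            class = "simulation_spec")
}

#' Simulate multi-subject responses from known kernels
#'
#' The generative model is the forward TRF model itself: each channel's
#' signal is the kernel convolution `sum_f gain_cf * (beta_f * x_f)(t)`,
#' shared across subjects (up to optional per-subject amplitude jitter),
#' plus band-limited 1/f Gaussian noise scaled so that the realized
#' signal-to-noise variance ratio equals `spec$snr`. With all-zero kernels
#' the response is pure noise at unit variance.
#'
#' @param predictors Predictor set (`F x T` matrix, list of
#'   `predictor_series`, or single series), sample rate matching
#'   `spec$grid`.
#' @param spec A [simulation_spec()].
#' @param seed RNG seed.
#' @param sample_rate Required for bare-matrix predictors.
#' @return List with `responses` (list of channels-by-time matrices, one
#'   per subject), `signal` (noise-free channels-by-time matrix), and
#'   `spec`.
#' @export
simulate_responses <- function(predictors, spec, seed = 1,
                               sample_rate = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  pm <- as_predictor_matrix(predictors, sample_rate)
  if (!isTRUE(all.equal(pm$sample_rate, spec$grid$sample_rate)))
    stop("predictor sample rate must match the simulation lag grid")
  x <- pm$x
  if (nrow(x) != length(spec$kernels))
    stop("number of kernels must match number of predictors")
  set.seed(seed)
  T_len <- ncol(x)
  C <- spec$n_channels
  ## per-predictor convolved signal, then per-channel mixing by gain
  conv_f <- matrix(0, nrow(x), T_len)
  for (f in seq_len(nrow(x)))
    conv_f[f, ] <- predict_response(matrix(spec$kernels[[f]], nrow = 1),
                                    x[f, , drop = FALSE], grid = spec$grid)
  signal <- spec$gains %*% conv_f                 # C x T
  sig_var <- apply(signal, 1, stats::var)
  ref_var <- if (any(sig_var > 0)) mean(sig_var[sig_var > 0]) else 1
  responses <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    amp <- if (spec$amp_jitter > 0)
      stats::rlnorm(1, -spec$amp_jitter^2 / 2, spec$amp_jitter) else 1
    y <- amp * signal
    for (ch in seq_len(C)) {
      nv <- if (sig_var[ch] > 0) sig_var[ch] / spec$snr else ref_var
      y[ch, ] <- y[ch, ] + sqrt(nv) *
        noise_1f(T_len, spec$grid$sample_rate, spec$noise_exponent,
                 spec$band)
    }
    responses[[s]] <- y
  }
  list(responses = responses, signal = signal, spec = spec)
}

#' Empirical collinearity of a predictor set
#'
#' Correlation matrix and variance inflation factors of the rows of a
#' predictor matrix — used to check that synthetic node-count predictors
#' reproduce the collinearity regime of real stimuli (strongly positively
#' correlated strategies).
#'
#' @param predictors `F x T` matrix or list of `predictor_series`.
#' @param sample_rate Required for bare matrices when given series.
#' @return List with `correlation` and `vif`.
#' @export
predictor_collinearity <- function(predictors, sample_rate = NULL) {
  pm <- as_predictor_matrix(predictors, sample_rate)
  r <- stats::cor(t(pm$x))
  list(correlation = r, vif = vif(r))
}
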