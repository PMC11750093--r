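#' Construct a predictor time series
#'
#' A `predictor_series` is a named, uniformly sampled regressor: either a
#' single channel (numeric vector) or a band-by-time matrix (acoustic
#' spectrogram-style predictors).
#'
#' @param values Numeric vector, or matrix with bands in rows.
#' @param sample_rate Sampling rate in Hz.
#' @param name Predictor name.
#' @return An object of class `predictor_series`.
#' @export
predictor_series <- function(values, sample_rate, name = "predictor") {
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("'sample_rate' must be positive")
  structure(list(values = values, sample_rate = sample_rate, name = name),
            class = "predictor_series")
}

#' @export
print.predictor_series <- function(x, ...) {
  dims <- if (is.matrix(x$values))
    sprintf("%d bands x %d samples", nrow(x$values), ncol(x$values))
  else sprintf("%d samples", length(x$values))
  cat(sprintf("<predictor_series> '%s': %s @ %g Hz\n", x$name, dims,
              x$sample_rate))
  invisible(x)
}

#' Impulse predictor from word onsets
#'
#' Places each value at the sample `floor(onset * sample_rate)` and zeros
#' everywhere else; values at coincident samples sum. This is the canonical
#' encoding of word-aligned quantities (node counts, surprisal, ...) as
#' regressors for a temporal response function.
#'
#' @param onsets Event times in seconds; must lie in `[0, duration)`.
#' @param values Value per event (recycled if length 1).
#' @param sample_rate Sampling rate in Hz.
#' @param duration Series duration in seconds.
#' @param name Predictor name.
#' @return A `predictor_series` of length `round(duration * sample_rate)`.
#' @export
impulse_series <- function(onsets, values, sample_rate, duration,
                           name = "impulse") {
  if (length(values) == 1L) values <- rep(values, length(onsets))
  if (length(onsets) != length(values))
    stop("'onsets' and 'values' must be aligned")
  n <- round(duration * sample_rate)
  if (length(onsets) && (any(onsets < 0) || any(onsets >= duration)))
    stop("onsets must lie in [0, duration)")
  x <- numeric(n)
  if (length(onsets)) {
    idx <- floor(onsets * sample_rate) + 1L
    for (i in seq_along(idx)) x[idx[i]] <- x[idx[i]] + values[i]
  }
  predictor_series(x, sample_rate, name)
}

#' Word-rate predictor
#'
#' An impulse series with value 1 at each word onset: the non-specific
#' "a word occurred here" regressor.
#'
#' @inheritParams impulse_series
#' @return A `predictor_series`.
#' @export
word_rate_series <- function(onsets, sample_rate, duration,
                             name = "word_rate") {
  impulse_series(onsets, rep(1, length(onsets)), sample_rate, duration, name)
}

#' Word-frequency predictor value (bits)
#'
#' `-log2` of the word's occurrence rate per million words, interpreted on a
#' 0-1 scale, so infrequent words get large values. Words missing from the
#' frequency database should be given the corpus minimum frequency by the
#' caller before calling this.
#'
#' @param per_million Frequency value(s) in `(0, 1]`; values above 1 are
#'   accepted with a warning (negative bits).
#' @return Numeric, bits.
#' @export
word_frequency <- function(per_million) {
  if (any(per_million <= 0)) stop("frequency must be positive")
  if (any(per_million > 1))
    warning("frequency > 1 on the 0-1 scale; yields negative bits")
  -log2(per_million)
}

#' Surprisal (bits)
#'
#' `-log2 P(w | context)`: how unexpected a word is given its context.
#'
#' @param p In-context probability in `(0, 1]`.
#' @return Numeric, bits.
#' @export
surprisal <- function(p) {
  if (any(p <= 0)) stop("probability must be positive")
  if (any(p > 1)) stop("probability must be <= 1")
  -log2(p)
}

#' Shannon entropy of a next-word distribution (bits)
#'
#' `H = -sum p log2 p` over the candidate next words; zero-probability terms
#' contribute 0. Quantifies the uncertainty about the upcoming word.
#'
#' @param dist Probability vector; must be non-negative and sum to 1
#'   (tolerance 1e-6).
#' @return Numeric scalar, bits.
#' @export
entropy <- function(dist) {
  if (any(dist < 0)) stop("negative probability mass")
  if (abs(sum(dist) - 1) > 1e-6) stop("distribution must sum to 1")
  p <- dist[dist > 0]
  -sum(p * log2(p))
}

## ERB-rate scale (Glasberg & Moore): number of equivalent rectangular
## bandwidths below frequency f (Hz).
hz_to_erb <- function(f) 21.4 * log10(0.00437 * f + 1)
erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' Gammatone envelope spectrogram
#'
#' Decomposes a mono waveform with a bank of 4th-order gammatone filters at
#' ERB-spaced centre frequencies, half-wave rectifies, low-pass filters and
#' resamples each band envelope to `out_rate`. This is the acoustic control
#' predictor: the band-limited energy envelope of the speech signal.
#'
#' @param wave Numeric mono waveform, or a list with elements `wave` and
#'   `sample_rate` (as returned by [read_wav()]).
#' @param sample_rate Input sampling rate in Hz (ignored if `wave` carries
#'   its own).
#' @param n_bands Number of bands. Default 8.
#' @param f_lo,f_hi Centre-frequency range in Hz. Defaults 20 and 5000.
#' @param out_rate Output envelope rate in Hz. Default 100.
#' @return A `predictor_series` whose values are an `n_bands` x time matrix
#'   of non-negative envelopes; row names give band centre frequencies.
#' @export
gammatone_envelope <- function(wave, sample_rate = NULL, n_bands = 8,
                               f_lo = 20, f_hi = 5000, out_rate = 100) {
  if (is.list(wave)) {
    sample_rate <- wave$sample_rate
    wave <- wave$wave
  }
  if (is.null(sample_rate)) stop("'sample_rate' required")
  if (!length(wave)) stop("empty audio")
  cf <- erb_to_hz(seq(hz_to_erb(f_lo), hz_to_erb(f_hi),
                      length.out = n_bands))
  fs <- sample_rate
  t_max <- 0.05                       # 50 ms impulse response is ample
  tt <- seq(0, t_max, by = 1 / fs)[-1]
  dec <- max(1L, floor(fs / out_rate))
  n_out <- floor(length(wave) * out_rate / fs)
  env <- matrix(0, n_bands, n_out)
  ## 4 Hz low-pass for the envelope-of-band signal before resampling
  lp <- signal::butter(2, min(0.9, 2 * (out_rate / 2) / fs), type = "low")
  for (b in seq_len(n_bands)) {
    erb_bw <- 24.7 * (0.00437 * cf[b] + 1)
    bcoef <- 1.019 * erb_bw
    g <- tt^3 * exp(-2 * pi * bcoef * tt) * cos(2 * pi * cf[b] * tt)
    g <- g / sqrt(sum(g^2))           # unit-energy kernel
    y <- stats::convolve(wave, rev(g), type = "open")
    y <- y[seq_along(wave)]
    y <- pmax(y, 0)                   # half-wave rectification
    y <- signal::filtfilt(lp, y)
    y <- pmax(y, 0)
    ## average-pool to out_rate
    idx <- floor((seq_along(y) - 1) * out_rate / fs) + 1L
    pooled <- tapply(y, idx, mean)
    env[b, ] <- as.numeric(pooled[seq_len(n_out)])
  }
  rownames(env) <- sprintf("%.0fHz", cf)
  predictor_series(env, out_rate, "gammatone_envelope")
}

#' Acoustic onset predictor
#'
#' A simplified acoustic edge detector: the half-wave-rectified first
#' temporal difference of each band envelope. Positive where band energy
#' rises, zero elsewhere. Designed as a plausible, swappable stand-in for
#' more elaborate auditory edge-detection front ends.
#'
#' @param envelope A band-by-time `predictor_series` (e.g. from
#'   [gammatone_envelope()]) or a non-negative matrix.
#' @param sample_rate Required if `envelope` is a bare matrix.
#' @return A `predictor_series` of the same shape, non-negative.
#' @export
acoustic_onsets <- function(envelope, sample_rate = NULL) {
  if (inherits(envelope, "predictor_series")) {
    sample_rate <- envelope$sample_rate
    env <- envelope$values
  } else env <- envelope
  if (is.null(sample_rate)) stop("'sample_rate' required")
  if (!is.matrix(env)) env <- matrix(env, nrow = 1)
  if (any(env < 0)) stop("envelope must be non-negative")
  d <- cbind(0, t(apply(env, 1, diff)))
  on <- pmax(d, 0)
  rownames(on) <- rownames(env)
  predictor_series(on, sample_rate, "acoustic_onsets")
}

#' Centre and scale a predictor or response series
#'
#' Subtracts the mean and divides by the mean absolute value, the
#' normalization applied to every predictor and every response channel
#' before TRF estimation. Idempotent.
#'
#' @param x A `predictor_series`, numeric vector, or matrix (rows are
#'   channels/bands, normalized per row).
#' @return Same type as the input, with per-channel mean 0 and mean
#'   absolute value 1.
#' @export
normalize_series <- function(x) {
  norm1 <- function(v) {
    v <- v - mean(v)
    mav <- mean(abs(v))
    if (mav == 0) stop("constant series cannot be normalized")
    v / mav
  }
  if (inherits(x, "predictor_series")) {
    vals <- if (is.matrix(x$values)) t(apply(x$values, 1, norm1))
            else norm1(x$values)
    if (is.matrix(x$values)) rownames(vals) <- rownames(x$values)
    return(predictor_series(vals, x$sample_rate, x$name))
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1, norm1))
    rownames(out) <- rownames(x)
    return(out)
  }
  norm1(x)
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 8/16/32-bit integer and 32-bit float PCM.
#' Multi-channel files are averaged to mono. Samples are scaled to
#' `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return A list with `wave` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels  = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate      = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits      = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: missing chunk")
  n <- length(data)
  x <- switch(as.character(fmt$bits),
    "8"  = (as.integer(data) - 128) / 128,
    "16" = readBin(data, integer(), n %/% 2, size = 2, signed = TRUE,
                   endian = "little") / 32768,
    "32" = if (fmt$format == 3)
             readBin(data, numeric(), n %/% 4, size = 4, endian = "little")
           else
             readBin(data, integer(), n %/% 4, size = 4,
                     endian = "little") / 2147483648,
    stop(sprintf("unsupported bit depth: %d", fmt$bits)))
  if (fmt$channels > 1) {
    x <- matrix(x, nrow = fmt$channels)
    x <- colMeans(x)
  }
  list(wave = as.numeric(x), sample_rate = fmt$rate)
}

#' Read a word-statistics table
#'
#' Tab-delimited file with columns `token`, `per_million` (frequency per
#' million words on the 0-1 scale) and `probability` (in-context
#' probability of the word).
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_word_statistics <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("token", "per_million", "probability")
  if (!all(need %in% names(df)))
    stop("word statistics table needs columns: ",
         paste(need, collapse = ", "))
  df
}
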