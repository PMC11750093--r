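#' Lag grid for temporal response functions
#'
#' Delays at which predictors are shifted against the response. The grid is
#' half-open: `K = round((tmax - tmin) * sample_rate)` delays
#' `tau_k = tmin + k / sample_rate`, `k = 0 .. K-1`, so `tmin` is included
#' and `tmax` excluded. With the defaults (-100 to 1000 ms at 100 Hz) this
#' yields K = 110 delays.
#'
#' @param tmin,tmax Lag window in seconds (`tmax > tmin`).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `lag_grid` with fields `tmin`, `tmax`,
#'   `sample_rate`, `K`, `tau` (delays in s) and `lag_samples` (integer
#'   sample offsets).
#' @examples
#' make_lag_grid(-0.1, 1.0, 100)$K  # 110
#' @export
make_lag_grid <- function(tmin = -0.1, tmax = 1.0, sample_rate = 100) {
  if (tmax <= tmin) stop("'tmax' must exceed 'tmin'")
  if (sample_rate <= 0) stop("'sample_rate' must be positive")
  K <- as.integer(round((tmax - tmin) * sample_rate))
  if (K < 1L) stop("lag window shorter than one sample")
  k <- seq_len(K) - 1L
  l0 <- as.integer(round(tmin * sample_rate))
  structure(list(tmin = tmin, tmax = tmax, sample_rate = sample_rate,
                 K = K, tau = tmin + k / sample_rate,
                 lag_samples = l0 + k),
            class = "lag_grid")
}

#' @export
print.lag_grid <- function(x, ...) {
  cat(sprintf("<lag_grid> [%g, %g) s @ %g Hz: K = %d delays\n",
              x$tmin, x$tmax, x$sample_rate, x$K))
  invisible(x)
}

## Hamming coefficient basis: `width` seconds wide, normalized to sum 1 so
## that basis expansion preserves impulse scale.
basis_window <- function(width, sample_rate) {
  n <- max(1L, as.integer(round(width * sample_rate)))
  if (n == 1L) return(1)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  w / sum(w)
}

## centered convolution with the basis window; zero-padded edges
smooth_basis <- function(x, w) {
  if (length(w) == 1L) return(x * w)
  y <- stats::filter(x, w, method = "convolution", sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

## coerce predictors to a named F x T matrix at a common sample rate
as_predictor_matrix <- function(x, sample_rate = NULL) {
  if (inherits(x, "predictor_series")) x <- list(x)
  if (is.list(x) && !is.data.frame(x)) {
    vals <- list(); nms <- character(0); sr <- sample_rate
    for (p in x) {
      if (!inherits(p, "predictor_series"))
        stop("list elements must be predictor_series")
      if (is.null(sr)) sr <- p$sample_rate
      if (!isTRUE(all.equal(sr, p$sample_rate)))
        stop("predictors have mismatched sample rates")
      v <- p$values
      if (is.matrix(v)) {
        bn <- rownames(v)
        if (is.null(bn)) bn <- paste0("b", seq_len(nrow(v)))
        for (b in seq_len(nrow(v))) {
          vals[[length(vals) + 1L]] <- v[b, ]
          nms <- c(nms, paste0(p$name, ".", bn[b]))
        }
      } else {
        vals[[length(vals) + 1L]] <- v
        nms <- c(nms, p$name)
      }
    }
    lens <- vapply(vals, length, integer(1))
    if (length(unique(lens)) != 1L)
      stop("predictors have mismatched lengths")
    m <- do.call(rbind, vals)
    rownames(m) <- nms
    return(list(x = m, sample_rate = sr))
  }
  if (is.numeric(x) && !is.matrix(x)) x <- matrix(x, nrow = 1)
  if (is.null(rownames(x))) rownames(x) <- paste0("x", seq_len(nrow(x)))
  if (is.null(sample_rate)) stop("'sample_rate' required for matrix input")
  list(x = x, sample_rate = sample_rate)
}

#' Predicted response from TRF kernels
#'
#' The forward model: `yhat(t) = sum_f sum_k beta_f(tau_k) x_f(t - tau_k)`,
#' with `x` treated as zero before the start of the recording.
#'
#' @param kernels Matrix of coefficients, predictors in rows and lags in
#'   columns (`F x K`), as returned by `coef()` on a fitted [trf()] model
#'   (one channel).
#' @param predictors Predictor set: `F x T` matrix, list of
#'   `predictor_series`, or single series. Row order must match `kernels`.
#' @param grid A `lag_grid`; defaults to the `grid` attribute of `kernels`.
#' @param sample_rate Required if `predictors` is a bare matrix.
#' @return Numeric vector `yhat` of length `T`.
#' @export
predict_response <- function(kernels, predictors, grid = attr(kernels, "grid"),
                             sample_rate = NULL) {
  if (is.null(grid)) stop("no lag grid supplied")
  pm <- as_predictor_matrix(predictors,
                            if (is.null(sample_rate)) grid$sample_rate
                            else sample_rate)
  if (!isTRUE(all.equal(pm$sample_rate, grid$sample_rate)))
    stop("predictor sample rate does not match the lag grid")
  x <- pm$x
  if (!is.matrix(kernels)) kernels <- matrix(kernels, nrow = 1)
  if (nrow(kernels) != nrow(x))
    stop("kernel rows must match predictor rows")
  if (ncol(kernels) != grid$K) stop("kernel columns must equal grid$K")
  T_len <- ncol(x)
  yhat <- numeric(T_len)
  for (f in seq_len(nrow(x))) {
    for (k in seq_len(grid$K)) {
      b <- kernels[f, k]
      if (b == 0) next
      L <- grid$lag_samples[k]
      src <- seq_len(T_len) - L
      ok <- src >= 1L & src <= T_len
      yhat[ok] <- yhat[ok] + b * x[f, src[ok]]
    }
  }
  yhat
}

#' Reconstruction accuracy
#'
#' Coefficient of determination on held-out data:
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, per channel.
#' Negative when the prediction is worse than the mean.
#'
#' @param y Observed signal: vector or channels-by-time matrix.
#' @param yhat Predicted signal, same shape.
#' @return Numeric vector of per-channel R^2.
#' @export
reconstruction_accuracy <- function(y, yhat) {
  if (!is.matrix(y)) { y <- matrix(y, nrow = 1); yhat <- matrix(yhat, nrow = 1) }
  if (!all(dim(y) == dim(yhat))) stop("'y' and 'yhat' must have equal shape")
  sapply(seq_len(nrow(y)), function(ch) {
    yy <- y[ch, ]
    sst <- sum((yy - mean(yy))^2)
    if (sst == 0) stop("constant response channel")
    1 - sum((yy - yhat[ch, ])^2) / sst
  })
}

#' Fit one TRF by boosting (single channel, explicit split)
#'
#' Greedy coordinate boosting of the TRF coefficients on a 50-ms Hamming
#' basis, minimising training l1 error, with selective stopping: a
#' predictor is frozen once every candidate increment for it would increase
#' the validation l1 error; the fit ends when all predictors are frozen or
#' `max_iter` is reached. Inputs are expected mean-centered and scaled to
#' unit mean absolute value (see [normalize_series()]); set
#' `normalize = TRUE` to have this done internally.
#'
#' @param predictors Predictor set (matrix `F x T`, list of
#'   `predictor_series`, or single series).
#' @param response Numeric vector, one channel.
#' @param train,validation Integer sample indices of the training and
#'   validation rows.
#' @param grid A `lag_grid`.
#' @param step Increment size as a fraction of the response mean absolute
#'   value. Default 0.005.
#' @param max_iter Iteration cap. Default 10000.
#' @param basis Basis window width in seconds. Default 0.05.
#' @param normalize Normalize predictors and response internally. Default
#'   `FALSE` (caller has normalized).
#' @param sample_rate Required for bare-matrix predictors.
#' @return A list with `kernel` (`F x K` matrix of TRF coefficients, with
#'   the lag grid attached as attribute `grid`), `h` (raw basis
#'   coefficients), `iterations`, `frozen`, and the final l1 errors.
#' @export
boost_fit <- function(predictors, response, train, validation, grid,
                      step = 0.005, max_iter = 10000, basis = 0.05,
                      normalize = FALSE, sample_rate = NULL) {
  pm <- as_predictor_matrix(predictors, sample_rate)
  x <- pm$x
  if (!isTRUE(all.equal(pm$sample_rate, grid$sample_rate)))
    stop("predictor sample rate does not match the lag grid")
  if (length(response) != ncol(x))
    stop("response length must match predictors")
  if (stats::sd(response) == 0) stop("degenerate constant response")
  if (normalize) {
    x <- normalize_series(x)
    response <- normalize_series(response)
  }
  w <- basis_window(basis, grid$sample_rate)
  xs <- t(apply(x, 1, smooth_basis, w = w))   # F x T
  fit <- boost_core(t(xs), response, as.integer(grid$lag_samples),
                    as.integer(train) - 1L, as.integer(validation) - 1L,
                    step * mean(abs(response)), as.integer(max_iter))
  h <- fit$h                                   # K x F
  kernel <- apply(h, 2, smooth_basis, w = w)   # K x F
  kernel <- t(kernel)                          # F x K
  rownames(kernel) <- rownames(x)
  attr(kernel, "grid") <- grid
  list(kernel = kernel, h = h, iterations = fit$iterations,
       frozen = stats::setNames(as.logical(fit$frozen), rownames(x)),
       train_l1 = fit$train_l1, val_l1 = fit$val_l1)
}

#' Fit a multivariate temporal response function model
#'
#' Estimates TRF kernels relating a set of predictor time series to each
#' channel of a continuous response, using coordinate boosting with
#' selective stopping under a 5-fold nested cross-validation scheme: the
#' time axis is split into `folds` contiguous equal segments; for each test
#' segment, four training runs rotate the validation segment over the
#' remaining four, the four resulting kernels are averaged, and the average
#' predicts the held-out test segment. Reconstruction accuracy is the
#' per-channel R^2 of those test predictions, averaged over folds. All
#' predictors and response channels are mean-centered and scaled by their
#' mean absolute value before fitting.
#'
#' @param x Predictors: list of [predictor_series()], a single series, or an
#'   `F x T` matrix (rows are predictors).
#' @param y Response: numeric vector or channels-by-time matrix.
#' @param sample_rate Sampling rate in Hz (required for bare matrices;
#'   otherwise taken from the predictor series).
#' @param tmin,tmax Lag window in seconds. Defaults -0.1 and 1.0.
#' @param folds Number of cross-validation segments. Default 5.
#' @param step Boosting increment as a fraction of the response mean
#'   absolute value. Default 0.005.
#' @param max_iter Boosting iteration cap per fit. Default 10000.
#' @param basis Hamming basis width in seconds. Default 0.05.
#' @return An object of class `trf`: a list with elements
#'   \describe{
#'     \item{kernels}{array `F x K x C` of TRF coefficients (grand average
#'       over folds), in normalized units.}
#'     \item{accuracy}{per-channel held-out R^2.}
#'     \item{grid}{the [make_lag_grid()] used.}
#'     \item{folds}{fold bookkeeping: segment bounds and the
#'       train/validation/test role of every segment in every run.}
#'     \item{fitted, y}{full-length predicted and observed (normalized)
#'       response, channels in rows.}
#'   }
#' @seealso [boost_fit()], [predict_response()], [reconstruction_accuracy()]
#' @export
trf <- function(x, y, sample_rate = NULL, tmin = -0.1, tmax = 1.0,
                folds = 5, step = 0.005, max_iter = 10000, basis = 0.05) {
  cl <- match.call()
  pm <- as_predictor_matrix(x, sample_rate)
  xm <- pm$x
  sr <- pm$sample_rate
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  if (ncol(y) != ncol(xm))
    stop("response and predictors must cover the same samples")
  grid <- make_lag_grid(tmin, tmax, sr)
  T_len <- ncol(xm)
  if (T_len < folds * grid$K)
    stop(sprintf("need at least folds * K = %d samples, got %d",
                 folds * grid$K, T_len))
  xm <- normalize_series(xm)
  yn <- normalize_series(y)

  w <- basis_window(basis, sr)
  xs <- t(apply(xm, 1, smooth_basis, w = w))   # F x T
  xs_t <- t(xs)                                # T x F for the core
  lags <- as.integer(grid$lag_samples)

  bounds <- floor(seq(0, T_len, length.out = folds + 1))
  seg_idx <- lapply(seq_len(folds),
                    function(i) (bounds[i] + 1L):bounds[i + 1L])

  F_n <- nrow(xm); C_n <- nrow(yn); K <- grid$K
  kernels <- array(0, dim = c(F_n, K, C_n),
                   dimnames = list(rownames(xm), NULL, rownames(y)))
  h_grand <- array(0, dim = c(K, F_n, C_n))
  acc <- matrix(NA_real_, C_n, folds)
  fitted <- matrix(0, C_n, T_len)
  iters <- 0L
  fold_map <- list()

  for (ch in seq_len(C_n)) {
    ych <- yn[ch, ]
    step_ch <- step * mean(abs(ych))
    for (test in seq_len(folds)) {
      rest <- setdiff(seq_len(folds), test)
      h_sum <- matrix(0, K, F_n)
      for (val in rest) {
        tr_segs <- setdiff(rest, val)
        tr_idx <- sort(unlist(seg_idx[tr_segs]))
        va_idx <- seg_idx[[val]]
        fit <- boost_core(xs_t, ych, lags, tr_idx - 1L, va_idx - 1L,
                          step_ch, as.integer(max_iter))
        h_sum <- h_sum + fit$h
        iters <- iters + fit$iterations
        if (ch == 1L)
          fold_map[[length(fold_map) + 1L]] <-
            data.frame(test = test, validation = val,
                       train = paste(tr_segs, collapse = ","))
      }
      h_fold <- h_sum / length(rest)
      yhat_full <- design_predict(xs_t, h_fold, lags)
      te_idx <- seg_idx[[test]]
      yy <- ych[te_idx]
      sst <- sum((yy - mean(yy))^2)
      acc[ch, test] <- 1 - sum((yy - yhat_full[te_idx])^2) / sst
      h_grand[, , ch] <- h_grand[, , ch] + h_fold / folds
    }
    hm <- matrix(h_grand[, , ch], K, F_n)
    kern <- t(apply(hm, 2, smooth_basis, w = w))
    if (F_n == 1L) kern <- matrix(kern, nrow = 1)
    kernels[, , ch] <- kern
    fitted[ch, ] <- design_predict(xs_t, hm, lags)
  }

  structure(list(
    call = cl, predictors = rownames(xm), grid = grid,
    kernels = kernels, h = h_grand,
    accuracy = stats::setNames(rowMeans(acc), rownames(y)),
    accuracy_by_fold = acc,
    folds = list(n = folds, bounds = bounds,
                 runs = do.call(rbind, fold_map)),
    fitted = fitted, y = yn,
    basis = basis, step = step, iterations = iters
  ), class = "trf")
}

#' @export
print.trf <- function(x, ...) {
  cat(sprintf("Boosted mTRF: %d predictor(s), %d channel(s), K = %d lags [%g, %g) s\n",
              length(x$predictors), length(x$accuracy), x$grid$K,
              x$grid$tmin, x$grid$tmax))
  cat(sprintf("  %d-fold CV reconstruction accuracy (R^2): mean %.4f, range [%.4f, %.4f]\n",
              x$folds$n, mean(x$accuracy), min(x$accuracy), max(x$accuracy)))
  invisible(x)
}

#' @export
summary.trf <- function(object, ...) {
  kn <- apply(abs(object$kernels), 1, sum)
  out <- list(
    predictors = object$predictors,
    n_channels = length(object$accuracy),
    grid = object$grid,
    accuracy = object$accuracy,
    kernel_l1 = kn,
    folds = object$folds$n
  )
  class(out) <- "summary.trf"
  out
}

#' @export
print.summary.trf <- function(x, ...) {
  cat(sprintf("Boosted mTRF fit (%d-fold CV, K = %d)\n", x$folds, x$grid$K))
  cat("Reconstruction accuracy (R^2) per channel:\n")
  print(round(x$accuracy, 4))
  cat("Kernel l1 mass per predictor (summed over lags and channels):\n")
  print(round(x$kernel_l1, 4))
  invisible(x)
}

#' @export
coef.trf <- function(object, channel = NULL, ...) {
  if (is.null(channel)) {
    k <- object$kernels
  } else {
    k <- object$kernels[, , channel, drop = FALSE][, , 1]
    if (length(object$predictors) == 1L) k <- matrix(k, nrow = 1)
    rownames(k) <- object$predictors
  }
  attr(k, "grid") <- object$grid
  k
}

#' @export
predict.trf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  pm <- as_predictor_matrix(newdata, object$grid$sample_rate)
  xm <- normalize_series(pm$x)
  C_n <- dim(object$kernels)[3]
  out <- matrix(0, C_n, ncol(xm))
  for (ch in seq_len(C_n))
    out[ch, ] <- predict_response(coef(object, channel = ch), xm,
                                  grid = object$grid)
  if (C_n == 1L) out[1, ] else out
}

#' @export
residuals.trf <- function(object, ...) {
  r <- object$y - object$fitted
  if (nrow(r) == 1L) r[1, ] else r
}

#' @export
fitted.trf <- function(object, ...) {
  f <- object$fitted
  if (nrow(f) == 1L) f[1, ] else f
}

#' Plot TRF kernels
#'
#' Draws the estimated response function of each predictor against lag, for
#' one channel or averaged over channels.
#'
#' @param x A fitted `trf` object.
#' @param channel Channel index, or `NULL` to average over channels.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.trf <- function(x, channel = NULL, ...) {
  k <- if (is.null(channel)) apply(x$kernels, c(1, 2), mean)
       else x$kernels[, , channel]
  if (!is.matrix(k)) k <- matrix(k, nrow = 1)
  graphics::matplot(x$grid$tau, t(k), type = "l", lty = 1,
                    xlab = "lag (s)", ylab = "TRF coefficient", ...)
  graphics::abline(v = 0, col = "grey", lty = 3)
  graphics::legend("topright", legend = x$predictors, lty = 1,
                   col = seq_along(x$predictors), cex = 0.7, bty = "n")
  invisible(x)
}
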