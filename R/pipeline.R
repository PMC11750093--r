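#' Model set for syntactic predictor comparison
#'
#' Defines the full model and the three null models, each omitting exactly
#' one syntactic predictor. Every model also contains all base (acoustic,
#' word-level and statistical) predictors, so a full-vs-null contrast
#' isolates the unique variance of one node-count predictor.
#'
#' @param base Character vector of base predictor names.
#' @param syntactic Character vector of the three syntactic predictor
#'   names, in the order bottom-up, top-down, left-corner.
#' @param include_base_models Also include the base-only model and the
#'   three base+one models. Default `FALSE`.
#' @return Named list mapping model name to its predictor-name vector.
#' @export
model_set <- function(base, syntactic, include_base_models = FALSE) {
  if (length(syntactic) != 3)
    stop("expected exactly 3 syntactic predictors")
  s <- syntactic
  models <- list()
  models[["full"]] <- c(base, s)
  nm <- c("bottomup_topdown", "bottomup_leftcorner", "topdown_leftcorner")
  omit <- c(3, 2, 1)  # model i omits syntactic predictor omit[i]
  for (i in 1:3) models[[nm[i]]] <- c(base, s[-omit[i]])
  if (include_base_models) {
    models[["base"]] <- base
    for (i in 1:3) models[[paste0("base_", s[i])]] <- c(base, s[i])
  }
  ## invariant: the full model is a superset of every null
  for (m in models)
    if (!all(m %in% models[["full"]])) stop("null model not nested in full")
  models
}

#' Fit a set of TRF models across subjects
#'
#' Orchestrates the model-comparison fits: for every model in the
#' configuration and every subject, fits a boosted mTRF via [trf()] and
#' collects per-subject, per-channel reconstruction accuracies and kernels.
#' Boosting is deterministic given the data, so reruns reproduce results
#' exactly; a manifest (configuration hash, versions, seeds) is attached.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{predictors}{named `F x T` matrix (rows named) or list of
#'       `predictor_series` with all candidate predictors.}
#'     \item{responses}{list of channels-by-time matrices, one per
#'       subject.}
#'     \item{sample_rate}{Hz.}
#'     \item{models}{named list from [model_set()] (or any name ->
#'       predictor-names mapping).}
#'     \item{tmin, tmax, folds, step, max_iter, basis}{optional [trf()]
#'       settings (paper-style defaults).}
#'     \item{seed}{optional integer recorded in the manifest.}
#'   }
#' @return An object of class `trf_model_set`: per-model lists of `trf`
#'   fits, per-model subjects-by-channels accuracy matrices, and the
#'   manifest.
#' @export
run_models <- function(config) {
  need <- c("predictors", "responses", "sample_rate", "models")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config missing: ", paste(miss, collapse = ", "))
  pm <- as_predictor_matrix(config$predictors, config$sample_rate)
  x_all <- pm$x
  for (m in config$models)
    if (!all(m %in% rownames(x_all)))
      stop("model references unknown predictors: ",
           paste(setdiff(m, rownames(x_all)), collapse = ", "))
  tmin <- config$tmin %||% -0.1
  tmax <- config$tmax %||% 1.0
  folds <- config$folds %||% 5
  step <- config$step %||% 0.005
  max_iter <- config$max_iter %||% 10000
  basis <- config$basis %||% 0.05

  n_subj <- length(config$responses)
  fits <- list()
  accuracy <- list()
  for (mname in names(config$models)) {
    preds <- config$models[[mname]]
    xm <- x_all[preds, , drop = FALSE]
    subj_fits <- vector("list", n_subj)
    acc <- NULL
    for (s in seq_len(n_subj)) {
      fit <- trf(xm, config$responses[[s]], sample_rate = pm$sample_rate,
                 tmin = tmin, tmax = tmax, folds = folds, step = step,
                 max_iter = max_iter, basis = basis)
      subj_fits[[s]] <- fit
      acc <- rbind(acc, fit$accuracy)
    }
    rownames(acc) <- paste0("subj", seq_len(n_subj))
    fits[[mname]] <- subj_fits
    accuracy[[mname]] <- acc
  }

  cfg_file <- tempfile()
  saveRDS(list(models = config$models, tmin = tmin, tmax = tmax,
               folds = folds, step = step, max_iter = max_iter,
               basis = basis, seed = config$seed), cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    n_subjects = n_subj,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("parsetrf")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  unlink(cfg_file)
  structure(list(fits = fits, accuracy = accuracy,
                 models = config$models, manifest = manifest),
            class = "trf_model_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trf_model_set <- function(x, ...) {
  cat(sprintf("<trf_model_set> %d model(s) x %d subject(s)\n",
              length(x$fits), x$manifest$n_subjects))
  for (m in names(x$accuracy))
    cat(sprintf("  %-22s mean R^2 = %.4f\n", m, mean(x$accuracy[[m]])))
  invisible(x)
}

## per-subject kernel array (S x C x K) for one predictor of one model
subject_kernels <- function(fits, predictor) {
  S <- length(fits)
  k1 <- coef(fits[[1]])
  C <- dim(k1)[3]; K <- dim(k1)[2]
  out <- array(0, dim = c(S, C, K))
  for (s in seq_len(S)) {
    ks <- coef(fits[[s]])
    f <- match(predictor, fits[[s]]$predictors)
    if (is.na(f)) stop("predictor not in model: ", predictor)
    out[s, , ] <- t(ks[f, , ])  # K x C -> C x K
  }
  out
}

#' Compare fitted models and build report tables
#'
#' For each syntactic predictor: (1) contrasts full-model vs null-model
#' reconstruction accuracy per subject and channel (graph-smoothed) and
#' runs the spatial cluster permutation test; (2) rectifies and
#' baseline-corrects the full-model TRFs of that predictor and runs the
#' spatiotemporal cluster permutation test; (3) averages accuracies over
#' each region of interest. Cluster alphas are Bonferroni-corrected for
#' the configured number of tests.
#'
#' @param results A `trf_model_set` from [run_models()]; must contain the
#'   `full` model and one null model per syntactic predictor.
#' @param graph A `channel_graph` matching the response channels.
#' @param contrasts Named list mapping syntactic predictor name to the
#'   name of the null model omitting it.
#' @param rois Optional named list of channel index vectors.
#' @param smooth_sd Graph smoothing width (hops). Default 1.
#' @param spatial_args,spatiotemporal_args Lists of overrides passed to
#'   [cluster_perm_spatial()] / [cluster_perm_spatiotemporal()].
#' @param n_tests Number of tests for the Bonferroni correction. Default
#'   `2 * length(contrasts)` (contrasts times two hemispheres in the
#'   original design; adjust to the actual family).
#' @param seed RNG seed for the permutations.
#' @return A list of class `trf_report` with elements `accuracy_clusters`,
#'   `trf_clusters`, `roi_accuracy`, `alpha` and `n_tests`.
#' @export
compare_and_report <- function(results, graph, contrasts, rois = NULL,
                               smooth_sd = 1, spatial_args = list(),
                               spatiotemporal_args = list(),
                               n_tests = 2 * length(contrasts),
                               seed = NULL) {
  stopifnot(inherits(results, "trf_model_set"))
  if (!"full" %in% names(results$fits)) stop("no 'full' model in results")
  S_full <- nrow(results$accuracy[["full"]])
  alpha <- bonferroni_alpha(n_tests)
  full_fits <- results$fits[["full"]]
  grid <- full_fits[[1]]$grid

  acc_cl <- list(); trf_cl <- list(); roi_rows <- list()
  for (pred in names(contrasts)) {
    nullm <- contrasts[[pred]]
    if (!nullm %in% names(results$accuracy))
      stop("missing null model: ", nullm)
    if (nrow(results$accuracy[[nullm]]) != S_full)
      stop("subject mismatch between full and ", nullm)
    dmap <- accuracy_contrast(results$accuracy[["full"]],
                              results$accuracy[[nullm]],
                              graph = graph, sd = smooth_sd)
    acc_cl[[pred]] <- do.call(cluster_perm_spatial,
      c(list(diff_maps = dmap, graph = graph, seed = seed), spatial_args))

    karr <- subject_kernels(full_fits, pred)          # S x C x K
    for (s in seq_len(dim(karr)[1]))
      karr[s, , ] <- graph_smooth(t(abs(karr[s, , ])), graph,
                                  sd = smooth_sd) |> t()
    kbc <- baseline_correct(karr, grid)
    trf_cl[[pred]] <- do.call(cluster_perm_spatiotemporal,
      c(list(x = kbc, graph = graph, sample_rate = grid$sample_rate,
             seed = seed), spatiotemporal_args))

    if (!is.null(rois)) {
      for (rname in names(rois)) {
        vals <- roi_summary(dmap, rois[[rname]])
        tt <- stats::t.test(vals)
        roi_rows[[length(roi_rows) + 1L]] <- data.frame(
          predictor = pred, roi = rname, mean_diff = mean(vals),
          se = stats::sd(vals) / sqrt(length(vals)),
          t = unname(tt$statistic), p = tt$p.value)
      }
    }
  }
  structure(list(
    accuracy_clusters = acc_cl,
    trf_clusters = trf_cl,
    roi_accuracy = if (length(roi_rows)) do.call(rbind, roi_rows) else NULL,
    alpha = alpha, n_tests = n_tests
  ), class = "trf_report")
}

#' @export
print.trf_report <- function(x, ...) {
  cat(sprintf("<trf_report> alpha = %.4f (Bonferroni, %d tests)\n",
              x$alpha, x$n_tests))
  for (pred in names(x$accuracy_clusters)) {
    tab <- x$accuracy_clusters[[pred]]$table
    sig <- sum(tab$p < x$alpha)
    cat(sprintf("  %-16s accuracy clusters: %d (%d significant)\n",
                pred, nrow(tab), sig))
  }
  if (!is.null(x$roi_accuracy)) {
    cat("ROI accuracy differences:\n")
    print(x$roi_accuracy, digits = 3)
  }
  invisible(x)
}
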