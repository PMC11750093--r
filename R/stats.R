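#' Channel adjacency graph
#'
#' Spatial neighbourhood structure over response channels, used for graph
#' smoothing and for forming clusters in permutation tests. Undirected, no
#' self-loops.
#'
#' @param n_channels Number of channels.
#' @param edges Two-column integer matrix of undirected edges (1-based
#'   channel ids).
#' @return An object of class `channel_graph` with fields `n`, `edges`
#'   (deduplicated, `i < j`) and `neighbors` (adjacency list).
#' @export
channel_graph <- function(n_channels, edges) {
  n_channels <- as.integer(n_channels)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (any(edges < 1L) || any(edges > n_channels))
    stop("edge endpoints out of range")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops not allowed")
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  nb <- vector("list", n_channels)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  structure(list(n = n_channels, edges = edges, neighbors = nb),
            class = "channel_graph")
}

#' @export
print.channel_graph <- function(x, ...) {
  cat(sprintf("<channel_graph> %d channels, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Rectangular lattice channel graph
#'
#' Convenience constructor: channels on an `nx` by `ny` grid with 4-connected
#' adjacency, a desk-scale stand-in for a sensor/source layout.
#'
#' @param nx,ny Grid dimensions.
#' @return A `channel_graph` with `nx * ny` channels (row-major ids).
#' @export
lattice_graph <- function(nx, ny = 1) {
  id <- function(i, j) (j - 1L) * nx + i
  e <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i < nx) e[[length(e) + 1L]] <- c(id(i, j), id(i + 1L, j))
    if (j < ny) e[[length(e) + 1L]] <- c(id(i, j), id(i, j + 1L))
  }
  channel_graph(nx * ny, do.call(rbind, e))
}

#' Read a channel graph from an edge-list file
#'
#' Plain-text file with two integer columns (1-based channel ids), one edge
#' per line; `#` comments allowed.
#'
#' @param path File path.
#' @param n_channels Total channel count (defaults to the largest id seen).
#' @return A `channel_graph`.
#' @export
read_channel_graph <- function(path, n_channels = NULL) {
  e <- utils::read.table(path, comment.char = "#")
  if (is.null(n_channels)) n_channels <- max(e)
  channel_graph(n_channels, as.matrix(e[, 1:2]))
}

#' Gaussian smoothing over a channel graph
#'
#' Heat-kernel smoothing: the graph analogue of convolving a spatial map
#' with a Gaussian of standard deviation `sd` (in graph hops). Implemented
#' as repeated symmetric diffusion steps
#' `y_i <- y_i + beta * sum_{j ~ i} (y_j - y_i)`, which preserves the
#' spatial mean exactly.
#'
#' @param x Numeric vector over channels, or a subjects-by-channels matrix
#'   (each row smoothed).
#' @param graph A `channel_graph`.
#' @param sd Smoothing width in hops. Default 1. `sd = 0` is the identity.
#' @return Smoothed `x`, same shape.
#' @export
graph_smooth <- function(x, graph, sd = 1) {
  stopifnot(inherits(graph, "channel_graph"))
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != graph$n) stop("columns of 'x' must match graph channels")
  if (sd > 0) {
    A <- matrix(0, graph$n, graph$n)
    A[graph$edges] <- 1
    A[graph$edges[, 2:1, drop = FALSE]] <- 1
    deg <- rowSums(A)
    dmax <- max(deg, 1)
    t_diff <- sd^2 / 2                 # heat-kernel time for variance sd^2
    beta_max <- 1 / (2 * dmax)         # stability bound
    n_steps <- max(1L, ceiling(t_diff / beta_max))
    beta <- t_diff / n_steps
    xt <- t(x)                         # channels x subjects
    for (s in seq_len(n_steps))
      xt <- xt + beta * (A %*% xt - deg * xt)
    x <- t(xt)
  }
  if (vec) x[1, ] else x
}

#' Variance inflation factors
#'
#' The diagonal of the inverse of the predictor correlation matrix:
#' `VIF_i = 1 / (1 - R^2_i)` where `R^2_i` is from regressing predictor i on
#' all others. VIF above ~5 signals multicollinearity severe enough to
#' destabilise TRF coefficient estimates.
#'
#' @param correlation_matrix Symmetric positive-definite matrix with unit
#'   diagonal (e.g. `cor(t(x))` of the predictor matrix).
#' @return Named numeric vector of VIFs (all `>= 1`).
#' @examples
#' vif(matrix(c(1, .8, .8, 1), 2))  # both 1/(1-0.64) = 2.778
#' @export
vif <- function(correlation_matrix) {
  m <- as.matrix(correlation_matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  inv <- tryCatch(solve(m), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(inv)) || any(diag(inv) <= 0)) {
    ev <- eigen(m, symmetric = TRUE)
    bad <- which(abs(ev$vectors[, ncol(m)]) > 1e-6)
    nm <- if (!is.null(colnames(m))) colnames(m)[bad] else bad
    stop("singular correlation matrix; collinear set: ",
         paste(nm, collapse = ", "))
  }
  out <- diag(inv)
  names(out) <- colnames(m)
  out
}

#' Full-vs-null reconstruction accuracy contrast
#'
#' Per-subject, per-channel difference between the reconstruction accuracy
#' of a full model and of a null model omitting one predictor. Both maps
#' are Gaussian-smoothed over the channel graph first (when a graph is
#' supplied), mirroring spatial smoothing of source maps.
#'
#' @param full,null Subjects-by-channels accuracy matrices, matched shapes.
#' @param graph Optional `channel_graph` for smoothing.
#' @param sd Smoothing width in hops. Default 1.
#' @return Subjects-by-channels difference matrix (`full - null`).
#' @export
accuracy_contrast <- function(full, null, graph = NULL, sd = 1) {
  if (!all(dim(full) == dim(null))) stop("shape mismatch")
  if (!is.null(graph)) {
    full <- graph_smooth(full, graph, sd)
    null <- graph_smooth(null, graph, sd)
  }
  full - null
}

## one-sample t per column for a subjects-by-points matrix, given per-subject
## signs (vector of +/-1); vectorized over points
signed_t <- function(x, signs) {
  s <- nrow(x)
  m <- as.numeric(signs %*% x) / s
  ssq <- colSums(x^2)
  v <- (ssq - s * m^2) / (s - 1)
  v[v <= 0] <- NA
  m / sqrt(v / s)
}

## connected components among `active` nodes (logical over graph nodes),
## using a neighbor list; returns list of integer vectors
components_active <- function(active, neighbors) {
  n <- length(active)
  seen <- logical(n)
  comps <- list()
  for (v in which(active)) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, u)
      for (w in neighbors[[u]]) {
        if (active[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

## clusters of one sign for a t-map over graph nodes; returns list of
## (members, stat)
t_clusters <- function(tmap, neighbors, tcrit, min_members, sign = 1L,
                       member_filter = NULL) {
  active <- !is.na(tmap) & (sign * tmap > tcrit)
  if (!any(active)) return(list())
  comps <- components_active(active, neighbors)
  out <- list()
  for (m in comps) {
    keep <- if (is.null(member_filter)) length(m) >= min_members
            else member_filter(m)
    if (keep)
      out[[length(out) + 1L]] <- list(members = m, stat = sum(tmap[m]))
  }
  out
}

new_cluster_result <- function(clusters, null_max, n_perm, extra = NULL) {
  if (length(clusters)) {
    tab <- data.frame(
      id = seq_along(clusters),
      n_points = vapply(clusters, function(c) length(c$members), integer(1)),
      t_sum = vapply(clusters, function(c) c$stat, numeric(1))
    )
    tab$t_av <- tab$t_sum / tab$n_points
    tab$p <- vapply(tab$t_sum, function(s)
      (1 + sum(null_max >= abs(s))) / (1 + n_perm), numeric(1))
  } else {
    tab <- data.frame(id = integer(0), n_points = integer(0),
                      t_sum = numeric(0), t_av = numeric(0), p = numeric(0))
  }
  structure(list(table = tab,
                 members = lapply(clusters, `[[`, "members"),
                 null_max = null_max, n_perm = n_perm, extra = extra),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations\n",
              nrow(x$table), x$n_perm))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Spatial cluster-based permutation test
#'
#' Nonparametric familywise test of whether per-subject difference maps
#' deviate from zero anywhere on the channel graph. Two-tailed one-sample
#' t-tests at each channel are thresholded at uncorrected
#' `p < cluster_alpha`; supra-threshold channels of common sign are
#' clustered by graph adjacency, clusters with at least `min_channels`
#' members are scored by the sum of their t-values, and each observed
#' cluster statistic is referred to the permutation distribution of the
#' maximum absolute cluster statistic under random within-subject sign
#' flips.
#'
#' @param diff_maps Subjects-by-channels matrix (e.g. from
#'   [accuracy_contrast()]).
#' @param graph A `channel_graph`.
#' @param cluster_alpha Cluster-forming (uncorrected, two-tailed) alpha.
#'   Default 0.05.
#' @param min_channels Minimum cluster size. Default 10.
#' @param n_perm Number of sign-flip permutations. Default 10000.
#' @param seed Optional RNG seed for the permutations.
#' @return A `cluster_result`: table with `n_points`, `t_sum`,
#'   `t_av = t_sum / n_points` and permutation `p`
#'   (`(1 + #exceedances) / (1 + n_perm)`), plus cluster memberships and the
#'   null distribution.
#' @export
cluster_perm_spatial <- function(diff_maps, graph, cluster_alpha = 0.05,
                                 min_channels = 10, n_perm = 10000,
                                 seed = NULL) {
  stopifnot(inherits(graph, "channel_graph"))
  x <- as.matrix(diff_maps)
  S <- nrow(x)
  if (S < 2) stop("need at least 2 subjects")
  if (ncol(x) != graph$n) stop("columns must match graph channels")
  if (!is.null(seed)) set.seed(seed)
  tcrit <- stats::qt(1 - cluster_alpha / 2, S - 1)

  tobs <- signed_t(x, rep(1, S))
  obs <- c(t_clusters(tobs, graph$neighbors, tcrit, min_channels, 1L),
           t_clusters(tobs, graph$neighbors, tcrit, min_channels, -1L))

  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), S, replace = TRUE)
    tp <- signed_t(x, signs)
    cl <- c(t_clusters(tp, graph$neighbors, tcrit, min_channels, 1L),
            t_clusters(tp, graph$neighbors, tcrit, min_channels, -1L))
    null_max[p] <- if (length(cl))
      max(abs(vapply(cl, `[[`, numeric(1), "stat"))) else 0
  }
  new_cluster_result(obs, null_max, n_perm)
}

#' Spatiotemporal cluster-based permutation test
#'
#' One-tailed test of whether rectified, baseline-corrected TRF
#' coefficients exceed zero anywhere in channel-by-lag space. Adjacency is
#' the channel graph crossed with adjacent lags; clusters must span at
#' least `min_channels` distinct channels and at least `min_time` seconds
#' of contiguous lags.
#'
#' @param x Subjects-by-channels-by-lags array (e.g. rectified TRFs after
#'   [baseline_correct()]).
#' @param graph A `channel_graph`.
#' @param sample_rate Lag-axis sampling rate in Hz (converts `min_time` to
#'   lag samples, rounded).
#' @param cluster_alpha Cluster-forming alpha (one-tailed). Default 0.025.
#' @param min_channels Minimum number of distinct channels. Default 40.
#' @param min_time Minimum lag span in seconds. Default 0.040.
#' @param n_perm Number of sign-flip permutations. Default 10000.
#' @param seed Optional RNG seed.
#' @return A `cluster_result`; `extra$nodes` maps node ids to
#'   (channel, lag) pairs.
#' @export
cluster_perm_spatiotemporal <- function(x, graph, sample_rate,
                                        cluster_alpha = 0.025,
                                        min_channels = 40, min_time = 0.040,
                                        n_perm = 10000, seed = NULL) {
  stopifnot(inherits(graph, "channel_graph"))
  d <- dim(x)
  if (length(d) != 3) stop("'x' must be subjects x channels x lags")
  S <- d[1]; C <- d[2]; L <- d[3]
  if (C != graph$n) stop("channel dimension must match graph")
  if (!is.null(seed)) set.seed(seed)
  min_lags <- max(1L, as.integer(round(min_time * sample_rate)))
  tcrit <- stats::qt(1 - cluster_alpha, S - 1)

  ## node id = (lag - 1) * C + channel
  node_ch <- rep(seq_len(C), L)
  node_lag <- rep(seq_len(L), each = C)
  nb <- vector("list", C * L)
  for (l in seq_len(L)) {
    off <- (l - 1L) * C
    for (ch in seq_len(C)) {
      ns <- graph$neighbors[[ch]] + off
      if (l > 1L) ns <- c(ns, off - C + ch)
      if (l < L)  ns <- c(ns, off + C + ch)
      nb[[off + ch]] <- ns
    }
  }
  xf <- matrix(aperm(x, c(1, 2, 3)), nrow = S)  # S x (C*L), lag-major

  filt <- function(members) {
    length(unique(node_ch[members])) >= min_channels &&
      (max(node_lag[members]) - min(node_lag[members]) + 1L) >= min_lags
  }

  tobs <- signed_t(xf, rep(1, S))
  obs <- t_clusters(tobs, nb, tcrit, NA, 1L, member_filter = filt)

  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), S, replace = TRUE)
    tp <- signed_t(xf, signs)
    cl <- t_clusters(tp, nb, tcrit, NA, 1L, member_filter = filt)
    null_max[p] <- if (length(cl))
      max(vapply(cl, `[[`, numeric(1), "stat")) else 0
  }
  res <- new_cluster_result(obs, null_max, n_perm,
                            extra = list(nodes = data.frame(
                              node = seq_len(C * L), channel = node_ch,
                              lag = node_lag)))
  ## channel/time extent per cluster
  if (nrow(res$table)) {
    res$table$n_channels <- vapply(res$members, function(m)
      length(unique(node_ch[m])), integer(1))
    res$table$lag_span <- vapply(res$members, function(m)
      max(node_lag[m]) - min(node_lag[m]) + 1L, integer(1))
  }
  res
}

#' Baseline-correct rectified TRF coefficients
#'
#' Takes the absolute value of the TRF coefficients and subtracts, per
#' channel, the mean over negative lags (the pre-onset interval), so that
#' post-onset deviations are measured against the pre-stimulus level.
#'
#' @param x Channels-by-lags matrix, or subjects-by-channels-by-lags array.
#' @param grid The `lag_grid` of the lag axis (must contain negative lags).
#' @return Same shape as `x`: `abs(x)` minus each channel's negative-lag
#'   mean.
#' @export
baseline_correct <- function(x, grid) {
  neg <- which(grid$tau < 0)
  if (!length(neg)) stop("lag grid contains no negative lags")
  if (is.matrix(x)) {
    a <- abs(x)
    a - rowMeans(a[, neg, drop = FALSE])
  } else if (length(dim(x)) == 3) {
    a <- abs(x)
    base <- apply(a[, , neg, drop = FALSE], c(1, 2), mean)
    sweep(a, c(1, 2), base, "-")
  } else stop("'x' must be a matrix or 3-d array")
}

#' Bonferroni-corrected alpha
#'
#' `family_alpha / n_tests`.
#'
#' @param n_tests Number of tests in the family (`>= 1`).
#' @param family_alpha Familywise alpha. Default 0.05.
#' @return Corrected per-test alpha.
#' @examples
#' round(bonferroni_alpha(6), 4)  # 0.0083
#' round(bonferroni_alpha(9), 4)  # 0.0056
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  if (n_tests < 1) stop("'n_tests' must be >= 1")
  family_alpha / n_tests
}

#' Region-of-interest summary
#'
#' Averages accuracy maps or TRF arrays over a channel subset.
#'
#' @param x Subjects-by-channels matrix (returns per-subject scalars),
#'   subjects-by-channels-by-lags array (returns subjects-by-lags curves),
#'   or channels-by-lags matrix (returns a lag curve).
#' @param roi_mask Integer or logical channel subset; must be non-empty.
#' @return Per-subject scalar vector, subjects-by-lags matrix, or lag
#'   curve, depending on the input shape.
#' @export
roi_summary <- function(x, roi_mask) {
  if (is.logical(roi_mask)) roi_mask <- which(roi_mask)
  if (!length(roi_mask)) stop("empty ROI mask")
  if (is.matrix(x))
    return(rowMeans(x[, roi_mask, drop = FALSE]))
  if (length(dim(x)) == 3)
    return(apply(x[, roi_mask, , drop = FALSE], c(1, 3), mean))
  stop("'x' must be a matrix or 3-d array")
}

#' Write a cluster table
#'
#' Tab-delimited export of a `cluster_result` table.
#'
#' @param result A `cluster_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
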