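#' Incremental node counts under three parsing strategies
#'
#' The same syntactic tree can be built by parsers that differ in *when* they
#' posit each constituent: a top-down parser posits (expands) a node before
#' any of its daughters, a bottom-up parser posits (reduces) it only after
#' all daughters are complete, and a left-corner parser posits (projects) it
#' after its first daughter. The per-word number of such actions —
#' incremental node count — is the complexity metric linking syntactic
#' structure to time-resolved neural signals.
#'
#' Attribution rules (terminal nodes are never counted):
#' \describe{
#'   \item{top-down}{every non-terminal is attributed to the leftmost
#'     terminal it dominates; equivalently, the number of opening brackets
#'     directly preceding a word in bracket notation.}
#'   \item{bottom-up}{every non-terminal is attributed to the rightmost
#'     terminal it dominates; the number of closing brackets directly
#'     following a word.}
#'   \item{left-corner}{a preterminal is attributed to its own terminal; a
#'     non-terminal with children is attributed to the rightmost terminal
#'     dominated by its first child (its left corner).}
#' }
#'
#' All three distributions sum to [count_nonterminals()] for every tree.
#' Counts are returned in leaf order, traces included; fold trace counts
#' onto their neighbouring words with [fold_trace_counts()].
#'
#' @param tree A `syntax_tree`.
#' @return An integer vector of per-leaf counts (one entry per terminal,
#'   traces included) with attributes `strategy` and `is_trace`.
#' @examples
#' tr <- parse_bracketed("(S (NP (D the) (N boy)) (VP (V sleeps)))")
#' node_count_top_down(tr)    # 3 1 2
#' node_count_bottom_up(tr)   # 1 2 3
#' node_count_left_corner(tr) # 2 2 2
#' @name node_counts
NULL

## Shared walker: assigns each non-terminal to a leaf index according to
## `attr_fun(node, left_idx, right_idx, first_child_right)`.
node_count_walk <- function(tree, strategy) {
  leaves <- tree_leaves(tree)
  n_leaf <- nrow(leaves)
  counts <- integer(n_leaf)
  next_leaf <- 1L
  ## returns c(leftmost, rightmost) leaf index spanned by node
  walk <- function(node) {
    if (is_leaf(node)) {
      idx <- next_leaf
      next_leaf <<- next_leaf + 1L
      ## the preterminal label itself is a countable node; under every
      ## strategy it is attributed to its own terminal
      counts[idx] <<- counts[idx] + 1L
      return(c(idx, idx))
    }
    spans <- lapply(node$children, walk)
    lo <- spans[[1L]][1L]
    hi <- spans[[length(spans)]][2L]
    target <- switch(strategy,
      top_down    = lo,
      bottom_up   = hi,
      left_corner = spans[[1L]][2L]  # rightmost leaf under first child
    )
    counts[target] <<- counts[target] + 1L
    c(lo, hi)
  }
  walk(tree)
  structure(counts, strategy = strategy, is_trace = leaves$is_trace)
}

#' @rdname node_counts
#' @export
node_count_top_down <- function(tree) node_count_walk(tree, "top_down")

#' @rdname node_counts
#' @export
node_count_bottom_up <- function(tree) node_count_walk(tree, "bottom_up")

#' @rdname node_counts
#' @export
node_count_left_corner <- function(tree) node_count_walk(tree, "left_corner")

#' Fold trace node counts onto neighbouring words
#'
#' Traces (empty elements) have no acoustic correlate, so their node counts
#' are reassigned: each trace's count is added to the next overt word;
#' traces in sentence-final position (no following word) are added to the
#' previous word. Consecutive traces accumulate onto the same target, and
#' the per-sentence total is preserved.
#'
#' @param counts Integer per-leaf counts, as returned by the
#'   `node_count_*()` functions (traces included, in leaf order).
#' @param is_trace Logical vector flagging trace leaves. Defaults to the
#'   `is_trace` attribute of `counts`.
#' @return Integer vector of per-word counts (one entry per overt word).
#' @examples
#' fold_trace_counts(c(2L, 3L, 1L), c(TRUE, FALSE, FALSE))  # 5 1
#' fold_trace_counts(c(3L, 1L, 2L), c(FALSE, FALSE, TRUE))  # 3 3
#' @export
fold_trace_counts <- function(counts, is_trace = attr(counts, "is_trace")) {
  if (is.null(is_trace))
    stop("'is_trace' missing and 'counts' carries no is_trace attribute")
  counts <- as.integer(counts)
  is_trace <- as.logical(is_trace)
  if (length(counts) != length(is_trace))
    stop("'counts' and 'is_trace' must be aligned")
  word_pos <- which(!is_trace)
  if (length(word_pos) == 0L)
    stop("sentence consists only of traces; no word to carry the counts")
  ## target word (in word numbering) for every leaf: next word if one
  ## follows, otherwise the previous word
  n <- length(counts)
  target <- integer(n)
  ## number of words at or after each position
  word_rank <- cumsum(!is_trace)           # words up to and including i
  for (i in seq_len(n)) {
    if (!is_trace[i]) {
      target[i] <- word_rank[i]
    } else {
      nxt <- word_rank[i] + 1L             # next word's rank, if any
      target[i] <- if (nxt <= length(word_pos)) nxt else word_rank[i]
    }
  }
  out <- integer(length(word_pos))
  for (i in seq_len(n)) out[target[i]] <- out[target[i]] + counts[i]
  out
}

#' Syntactic information rate
#'
#' The rate at which syntactically demanding words arrive: words whose node
#' count exceeds `threshold` are selected, and each rate is the reciprocal
#' of the inter-onset interval between consecutive selected words. In
#' naturalistic speech this rate falls largely within the 0.5-4 Hz delta
#' band, motivating the delta-band analysis of the neural signal.
#'
#' @param onsets Word onset times in seconds, strictly increasing, aligned
#'   with `counts`.
#' @param counts Per-word node counts (after trace folding).
#' @param threshold Words with `counts > threshold` are selected (strict
#'   comparison). Default 2.
#' @return A list with `rates` (Hz, one per consecutive selected pair;
#'   empty if fewer than 2 words selected), `median` (Hz; `NA` when
#'   undefined), and `n_selected`.
#' @examples
#' syntactic_rate(c(1, 1.5, 3), c(3, 4, 1))  # one interval of 0.5 s -> 2 Hz
#' @export
syntactic_rate <- function(onsets, counts, threshold = 2L) {
  if (length(onsets) != length(counts))
    stop("'onsets' and 'counts' must be aligned")
  if (length(onsets) > 1L && any(diff(onsets) <= 0))
    stop("'onsets' must be strictly increasing")
  sel <- which(counts > threshold)
  if (length(sel) < 2L)
    return(list(rates = numeric(0), median = NA_real_,
                n_selected = length(sel)))
  rates <- 1 / diff(onsets[sel])
  list(rates = rates, median = stats::median(rates), n_selected = length(sel))
}

#' Kernel density of syntactic information rates
#'
#' Gaussian kernel density over rates in Hz, bandwidth by Silverman's rule
#' (`bw.nrd0`). Used to visualise how the rate distribution of each parsing
#' strategy relates to the delta band.
#'
#' @param rates Numeric vector of rates in Hz.
#' @param ... Passed on to [stats::density()].
#' @return A `density` object.
#' @export
rate_density <- function(rates, ...) {
  if (length(rates) < 2L) stop("need at least 2 rates for a density")
  stats::density(rates, bw = "nrd0", kernel = "gaussian", ...)
}

#' Per-word node-count table for a corpus
#'
#' Runs all three parsing strategies over a list of trees, folds trace
#' counts onto overt words, and returns one row per overt word. If a
#' timing table is supplied (columns `onset`, `offset`; one row per overt
#' word across the corpus, in order), onsets/offsets are attached.
#'
#' @param trees List of `syntax_tree` objects.
#' @param timings Optional data frame with `onset` and `offset` columns.
#' @return A data frame with columns `sentence`, `word`, `token`,
#'   `nc_topdown`, `nc_bottomup`, `nc_leftcorner`, and (if supplied)
#'   `onset`, `offset`.
#' @export
node_count_table <- function(trees, timings = NULL) {
  rows <- lapply(seq_along(trees), function(s) {
    tr <- trees[[s]]
    leaves <- tree_leaves(tr)
    is_tr <- leaves$is_trace
    if (all(is_tr)) stop(sprintf("sentence %d consists only of traces", s))
    td <- fold_trace_counts(node_count_top_down(tr), is_tr)
    bu <- fold_trace_counts(node_count_bottom_up(tr), is_tr)
    lc <- fold_trace_counts(node_count_left_corner(tr), is_tr)
    tok <- leaves$token[!is_tr]
    data.frame(sentence = s, word = seq_along(tok), token = tok,
               nc_topdown = td, nc_bottomup = bu, nc_leftcorner = lc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(timings)) {
    if (nrow(timings) != nrow(out))
      stop("timing table must have one row per overt word")
    out$onset <- timings$onset
    out$offset <- timings$offset
  }
  out
}

#' Write a per-word node-count table
#'
#' Tab-delimited output of [node_count_table()].
#'
#' @param table Data frame from [node_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-word table
#'
#' @param path Tab-delimited file written by [write_word_table()] (or any
#'   word-timing table with `word`, `onset`, `offset` columns).
#' @return A data frame.
#' @export
read_word_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
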