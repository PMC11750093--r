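# Independent oracles and fixture generators used across the test files.
# These deliberately take different computational routes from the package
# implementation (string tallies, stack-machine simulation, brute force).

# --- bracket-string tallies -------------------------------------------------
# Top-down / bottom-up node counts straight off the serialized bracket
# string: number of opening brackets directly preceding a terminal, and
# closing brackets directly following it.  An atom right after "(" is a
# category label; any other atom is a terminal.
bracket_tally_oracle <- function(bracket_string) {
  toks <- regmatches(bracket_string,
                     gregexpr("\\(|\\)|[^()\\s]+", bracket_string,
                              perl = TRUE))[[1]]
  is_term <- logical(length(toks))
  prev <- ""
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (t != "(" && t != ")" && prev != "(") is_term[i] <- TRUE
    prev <- t
  }
  term_idx <- which(is_term)
  td <- integer(length(term_idx))
  bu <- integer(length(term_idx))
  for (w in seq_along(term_idx)) {
    i <- term_idx[w]
    # opening brackets back to the previous terminal (labels skipped)
    j <- i - 1L
    while (j >= 1 && !is_term[j]) {
      if (toks[j] == "(") td[w] <- td[w] + 1L
      if (toks[j] == ")") break
      j <- j - 1L
    }
    # closing brackets forward to the next non-")" token
    j <- i + 1L
    while (j <= length(toks) && toks[j] == ")") {
      bu[w] <- bu[w] + 1L
      j <- j + 1L
    }
  }
  list(top_down = td, bottom_up = bu)
}

# --- left-corner stack-machine simulator ------------------------------------
# Replays an arc-eager left-corner parse of a known tree with a perfect
# oracle: terminals are shifted in order; completing a constituent that is
# the left corner (first child) of its yet-unannounced parent projects that
# parent (one counted action at the current word); completed non-initial
# children attach to their announced parent.  Returns project actions per
# word, including the projection of each preterminal from its terminal.
left_corner_simulator <- function(tree) {
  # flatten to id arrays
  parent <- integer(0); childpos <- integer(0); nkids <- integer(0)
  leaf_of <- integer(0)  # leaf index for leaf nodes, 0 otherwise
  n_nodes <- 0L
  n_leaves <- 0L
  build <- function(node, par, pos) {
    n_nodes <<- n_nodes + 1L
    id <- n_nodes
    parent[id] <<- par; childpos[id] <<- pos
    if (!is.null(node$terminal)) {
      n_leaves <<- n_leaves + 1L
      leaf_of[id] <<- n_leaves
      nkids[id] <<- 0L
    } else {
      leaf_of[id] <<- 0L
      nkids[id] <<- length(node$children)
      for (c in seq_along(node$children)) build(node$children[[c]], id, c)
    }
    id
  }
  build(unclass(tree), 0L, 1L)

  counts <- integer(n_leaves)
  announced <- logical(n_nodes)
  done <- integer(n_nodes)
  current_word <- 0L
  complete <- function(id) {
    p <- parent[id]
    if (p == 0L) return(invisible())
    if (!announced[p]) {
      stopifnot(childpos[id] == 1L)           # left corner of its parent
      announced[p] <<- TRUE
      counts[current_word] <<- counts[current_word] + 1L  # project parent
      done[p] <<- 1L
    } else {
      done[p] <<- done[p] + 1L
    }
    if (done[p] == nkids[p]) complete(p)
  }
  leaf_ids <- which(leaf_of > 0L)
  leaf_ids <- leaf_ids[order(leaf_of[leaf_ids])]
  for (id in leaf_ids) {
    current_word <- leaf_of[id]
    counts[current_word] <- counts[current_word] + 1L  # project preterminal
    announced[id] <- TRUE
    complete(id)
  }
  counts
}

# --- random trees (independent of the package generator) --------------------
labels_pool <- c("S", "NP", "VP", "PP", "AP", "N1", "V1", "X")
pos_pool <- c("N", "V", "D", "P", "A")

random_tree <- function(n_leaves, unary_prob = 0.15, trace_prob = 0.1) {
  mk <- function(n) {
    if (n == 1) {
      lf <- if (stats::runif(1) < trace_prob)
        parsetrf::syntax_tree(sample(labels_pool, 1), terminal = "t",
                              trace = TRUE)
      else
        parsetrf::syntax_tree(sample(pos_pool, 1),
                              terminal = paste0("w", sample(999, 1)))
      if (stats::runif(1) < unary_prob)
        lf <- parsetrf::syntax_tree(sample(labels_pool, 1),
                                    children = list(lf))
      return(lf)
    }
    k <- sample(2:min(n, 4), 1)
    sizes <- as.vector(stats::rmultinom(1, n - k, rep(1 / k, k))) + 1L
    node <- parsetrf::syntax_tree(sample(labels_pool, 1),
                                  children = lapply(sizes, mk))
    if (stats::runif(1) < unary_prob)
      node <- parsetrf::syntax_tree(sample(labels_pool, 1),
                                    children = list(node))
    node
  }
  mk(n_leaves)
}

# all ordered trees with n leaves whose internal nodes have >= 2 children
# (little-Schroeder enumeration), labels fixed; leaves are words
enumerate_trees <- function(n) {
  if (n == 1)
    return(list(parsetrf::syntax_tree("N", terminal = "w")))
  out <- list()
  # compositions of n into k >= 2 parts
  compositions <- function(n, k) {
    if (k == 1) return(list(n))
    res <- list()
    for (first in 1:(n - k + 1))
      for (rest in compositions(n - first, k - 1))
        res[[length(res) + 1L]] <- c(first, rest)
    res
  }
  for (k in 2:n) {
    for (comp in compositions(n, k)) {
      kid_sets <- lapply(comp, enumerate_trees)
      idx <- lapply(kid_sets, seq_along)
      grid <- expand.grid(idx)
      for (r in seq_len(nrow(grid))) {
        kids <- lapply(seq_len(k), function(j)
          kid_sets[[j]][[grid[r, j]]])
        out[[length(out) + 1L]] <-
          parsetrf::syntax_tree("X", children = kids)
      }
    }
  }
  out
}

# --- misc -------------------------------------------------------------------
# brute-force syntactic rate: two explicit passes
rate_brute_force <- function(onsets, counts, threshold = 2) {
  sel_on <- c()
  for (i in seq_along(counts))
    if (counts[i] > threshold) sel_on <- c(sel_on, onsets[i])
  if (length(sel_on) < 2) return(numeric(0))
  r <- numeric(0)
  for (i in 2:length(sel_on)) r <- c(r, 1 / (sel_on[i] - sel_on[i - 1]))
  r
}

# simple smooth test kernel on a lag grid, zero at negative lags
gauss_kernel <- function(grid, peak = 0.15, width = 0.08, amp = 1) {
  k <- amp * exp(-((grid$tau - peak) / width)^2)
  k[grid$tau < 0] <- 0
  k
}
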