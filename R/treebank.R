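#' Construct a syntactic tree node
#'
#' A `syntax_tree` is a rooted, ordered, labelled tree. A node carries either
#' a terminal (a word string, or a trace marker for a phonologically empty
#' element) or one or more child nodes, never both. Category labels are
#' opaque strings; no phrase-structure well-formedness beyond tree validity
#' is enforced, so arbitrary unary chains are accepted.
#'
#' @param label Category label (e.g. `"S"`, `"NP"`, `"D"`).
#' @param children List of `syntax_tree` children, or `NULL` for a leaf.
#' @param terminal Terminal word string, or `NULL` for an internal node.
#' @param trace Logical; `TRUE` marks the terminal as a trace (empty element).
#' @return An object of class `syntax_tree`.
#' @export
syntax_tree <- function(label, children = NULL, terminal = NULL, trace = FALSE) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a non-empty string")
  has_term <- !is.null(terminal)
  has_kids <- !is.null(children) && length(children) > 0L
  if (has_term == has_kids)
    stop("a node must have either a terminal or >= 1 child, never both or neither")
  if (trace && !has_term)
    stop("only a terminal node can be a trace")
  if (has_kids) {
    ok <- vapply(children, inherits, logical(1), what = "syntax_tree")
    if (!all(ok)) stop("all children must be syntax_tree objects")
  }
  structure(
    list(label = label, children = children, terminal = terminal,
         trace = isTRUE(trace)),
    class = "syntax_tree"
  )
}

#' @export
print.syntax_tree <- function(x, ...) {
  cat("<syntax_tree> ", write_bracketed(x), "\n", sep = "")
  invisible(x)
}

is_leaf <- function(node) !is.null(node$terminal)

#' Parse a bracketed tree string
#'
#' Reads one sentence in Penn-Treebank-style bracket notation, e.g.
#' `"(S (NP (D the) (N boy)) (VP (V sleeps)))"`. A terminal equal to
#' `trace_marker` is flagged as a trace (an empty element with no acoustic
#' correlate).
#'
#' @param text Bracket-notation string; must be balanced and non-empty.
#' @param trace_marker Terminal token that encodes a trace. Default `"t"`.
#' @return A `syntax_tree`.
#' @seealso [write_bracketed()], [read_treebank()]
#' @examples
#' tr <- parse_bracketed("(S (NP (D the) (N boy)) (VP (V sleeps)))")
#' count_nonterminals(tr)
#' @export
parse_bracketed <- function(text, trace_marker = "t") {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L

  skip_ws <- function() {
    while (pos <= n && chars[pos] %in% c(" ", "\t", "\n", "\r")) pos <<- pos + 1L
  }
  read_atom <- function() {
    start <- pos
    while (pos <= n && !chars[pos] %in% c("(", ")", " ", "\t", "\n", "\r"))
      pos <<- pos + 1L
    if (pos == start)
      stop(sprintf("parse error at offset %d: expected a token", start))
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  parse_node <- function() {
    skip_ws()
    if (pos > n || chars[pos] != "(")
      stop(sprintf("parse error at offset %d: expected '('", pos))
    open_at <- pos
    pos <<- pos + 1L
    skip_ws()
    if (pos > n)
      stop(sprintf("parse error at offset %d: unbalanced brackets", open_at))
    if (chars[pos] == ")")
      stop(sprintf("parse error at offset %d: empty constituent", pos))
    label <- read_atom()
    children <- list()
    terminal <- NULL
    repeat {
      skip_ws()
      if (pos > n)
        stop(sprintf("parse error at offset %d: unbalanced brackets", open_at))
      ch <- chars[pos]
      if (ch == ")") {
        pos <<- pos + 1L
        break
      } else if (ch == "(") {
        if (!is.null(terminal))
          stop(sprintf("parse error at offset %d: node mixes terminal and children", pos))
        children[[length(children) + 1L]] <- parse_node()
      } else {
        if (length(children) > 0L)
          stop(sprintf("parse error at offset %d: node mixes terminal and children", pos))
        if (!is.null(terminal))
          stop(sprintf("parse error at offset %d: multiple terminals under one label", pos))
        terminal <- read_atom()
      }
    }
    if (is.null(terminal) && length(children) == 0L)
      stop(sprintf("parse error at offset %d: empty constituent", open_at))
    if (!is.null(terminal))
      syntax_tree(label, terminal = terminal,
                  trace = identical(terminal, trace_marker))
    else
      syntax_tree(label, children = children)
  }

  skip_ws()
  if (pos > n) stop("parse error: empty input")
  tree <- parse_node()
  skip_ws()
  if (pos <= n)
    stop(sprintf("parse error at offset %d: trailing content", pos))
  tree
}

#' Serialize a tree to bracket notation
#'
#' Inverse of [parse_bracketed()]: `parse_bracketed(write_bracketed(t))` is
#' structurally identical to `t` (modulo whitespace).
#'
#' @param tree A `syntax_tree`.
#' @return A single bracket-notation string.
#' @export
write_bracketed <- function(tree) {
  stopifnot(inherits(tree, "syntax_tree"))
  if (is_leaf(tree))
    paste0("(", tree$label, " ", tree$terminal, ")")
  else
    paste0("(", tree$label, " ",
           paste(vapply(tree$children, write_bracketed, character(1)),
                 collapse = " "),
           ")")
}

#' Count non-terminal nodes
#'
#' Counts every non-leaf node of the tree, preterminals included, terminal
#' (word/trace) nodes excluded. This is the total amount of structure a
#' parser builds for the sentence, and therefore the common budget that the
#' top-down, bottom-up and left-corner strategies distribute differently
#' over time.
#'
#' A node holding a terminal contributes its preterminal label (the word
#' itself is not counted), so `"(N dog)"` has exactly one non-terminal, N.
#'
#' @param tree A `syntax_tree`.
#' @return Integer count of non-terminal nodes.
#' @export
count_nonterminals <- function(tree) {
  stopifnot(inherits(tree, "syntax_tree"))
  if (is_leaf(tree)) return(1L)  # the preterminal label
  1L + sum(vapply(tree$children, count_nonterminals, integer(1)))
}

#' Leaf sequence of a tree
#'
#' Returns the terminals in sentence order, traces interleaved at their
#' structural position.
#'
#' @param tree A `syntax_tree`.
#' @return A data frame with columns `token` (character) and `is_trace`
#'   (logical), one row per leaf.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "syntax_tree"))
  toks <- character(0)
  trc <- logical(0)
  walk <- function(node) {
    if (is_leaf(node)) {
      toks[length(toks) + 1L] <<- node$terminal
      trc[length(trc) + 1L] <<- node$trace
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree)
  data.frame(token = toks, is_trace = trc, stringsAsFactors = FALSE)
}

#' Read a treebank file
#'
#' One bracketed sentence per line, UTF-8; lines starting with `#` and blank
#' lines are ignored.
#'
#' @param path File path.
#' @param trace_marker Passed to [parse_bracketed()].
#' @return A list of `syntax_tree` objects.
#' @export
read_treebank <- function(path, trace_marker = "t") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_bracketed, trace_marker = trace_marker)
}

#' Write a treebank file
#'
#' @param trees List of `syntax_tree` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_treebank <- function(trees, path) {
  writeLines(vapply(trees, write_bracketed, character(1)), path,
             useBytes = TRUE)
  invisible(path)
}
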