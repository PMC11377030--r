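# Canonical in-memory rooted tree.
#
# A node is a plain list with fields
#   label       : character(1) or NULL
#   edge_length : numeric(1), NA when the edge to the parent has no length
#   children    : ordered list of child nodes (empty for a leaf)
#   payload     : optional collapse bookkeeping (see collapse.R)
# The tree object (class "collapser_tree") wraps the root and caches
# has_lengths. Trees are always treated as rooted, exactly as given.

new_node <- function(label = NULL, edge_length = NA_real_, children = list(),
                     payload = NULL) {
  list(label = label, edge_length = edge_length, children = children,
       payload = payload)
}

is_leaf_node <- function(node) length(node$children) == 0L

#' Construct a rooted tree from a node structure
#'
#' Wraps a root node into a `collapser_tree` object, validating the tree
#' invariants: every leaf has a non-empty label, leaf labels are unique,
#' and edge lengths (where present) are non-negative.
#'
#' @param root a node list as produced by the parsers in this package.
#' @return an object of class `collapser_tree` with elements `root` and
#'   `has_lengths` (`TRUE` iff every non-root edge carries a length).
#' @keywords internal
new_tree <- function(root) {
  validate_node(root)
  labs <- leaf_labels_node(root)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup) > 0L) {
    stop_tc("duplicate_labels",
            sprintf("duplicate leaf labels are not allowed: %s",
                    paste(dup, collapse = ", ")))
  }
  # a single-node tree has no internal edges: it carries lengths only if
  # its own (root) edge does
  has_lengths <- if (is_leaf_node(root)) {
    !is.na(root$edge_length)
  } else {
    node_has_lengths(root, is_root = TRUE)
  }
  structure(
    list(root = root, has_lengths = has_lengths),
    class = "collapser_tree"
  )
}

validate_node <- function(node, depth = 0L) {
  if (is_leaf_node(node) && (is.null(node$label) || !nzchar(node$label))) {
    stop_tc("invalid_tree", "leaf node without a label")
  }
  if (!is.na(node$edge_length) && node$edge_length < 0) {
    stop_tc("invalid_tree",
            sprintf("negative edge length (%g) on node '%s'",
                    node$edge_length,
                    if (is.null(node$label)) "<unnamed>" else node$label))
  }
  for (ch in node$children) validate_node(ch, depth + 1L)
  invisible(TRUE)
}

node_has_lengths <- function(node, is_root = FALSE) {
  if (!is_root && is.na(node$edge_length)) return(FALSE)
  for (ch in node$children) {
    if (!node_has_lengths(ch)) return(FALSE)
  }
  TRUE
}

# Leaves of a node, left to right, as a list of node structures.
collect_leaves <- function(node) {
  if (is_leaf_node(node)) return(list(node))
  out <- list()
  for (ch in node$children) out <- c(out, collect_leaves(ch))
  out
}

leaf_labels_node <- function(node) {
  vapply(collect_leaves(node), function(n) n$label, character(1))
}

#' Leaf labels of a tree
#'
#' @param tree a `collapser_tree`.
#' @return character vector of leaf labels in left-to-right order.
#' @export
leaf_labels <- function(tree) {
  stopifnot(inherits(tree, "collapser_tree"))
  leaf_labels_node(tree$root)
}

#' Count the terminal nodes of a tree
#'
#' @param tree a `collapser_tree`.
#' @return a single non-negative integer: the number of leaves (terminal
#'   branches, i.e. sequences) in the tree.
#' @examples
#' count_leaves(parse_tree("(A:0.1,B:0.2);"))  # 2
#' @export
count_leaves <- function(tree) {
  stopifnot(inherits(tree, "collapser_tree"))
  count_leaves_node(tree$root)
}

count_leaves_node <- function(node) {
  if (is_leaf_node(node)) return(1L)
  sum(vapply(node$children, count_leaves_node, integer(1)))
}

count_nodes <- function(node) {
  1L + sum(vapply(node$children, count_nodes, integer(1)))
}

#' @export
print.collapser_tree <- function(x, ...) {
  cat(sprintf("Rooted phylogenetic tree: %d leaves, %d nodes, branch lengths: %s\n",
              count_leaves(x), count_nodes(x$root),
              if (x$has_lengths) "yes" else "no"))
  nwk <- write_tree(x, mode = if (x$has_lengths) "phylogram" else "cladogram")
  if (nchar(nwk) > 70) nwk <- paste0(substr(nwk, 1, 67), "...")
  cat(" ", nwk, "\n")
  invisible(x)
}

# Classed errors so the CLI can map condition classes onto exit codes.
stop_tc <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("tc_", class), "tc_error", "error", "condition"),
    list(message = message, call = call)
  ))
}
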