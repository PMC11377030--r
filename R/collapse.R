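# Core collapsing algorithm.
#
# Sibling clades are merged when (i) the lowest common taxonomic ancestor
# of all their member sequences sits at or below every member's first
# stop term, and (ii) the merge would not put two sequences of the same
# species into one group (preserving all within-species duplication
# signal). Merging runs in a deterministic post-order, left-to-right;
# at each internal node sibling pairs are retested after every merge
# until none is collapsible, so the returned tree is a fixpoint.

#' Lowest common ancestor of a set of lineages
#'
#' The most specific taxonomy term present in every lineage, found by
#' scanning the first lineage from its most specific term upward.
#'
#' @param lineages non-empty list of lineages (character vectors, most
#'   specific term first).
#' @return the shared term. If the lineages share no term a classed error
#'   (`tc_disjoint_lineages`) is signaled; callers treating that case as
#'   "not collapsible" should catch it.
#' @examples
#' taxon_lca(list(
#'   c("Bactrocera_latifrons", "Tephritidae", "Acalyptratae", "Diptera"),
#'   c("Drosophila_melanogaster", "Drosophilidae", "Acalyptratae", "Diptera")))
#' @export
taxon_lca <- function(lineages) {
  stopifnot(is.list(lineages), length(lineages) > 0L)
  first <- lineages[[1]]
  for (term in first) {
    shared <- TRUE
    for (lin in lineages[-1]) {
      if (!(term %in% lin)) {
        shared <- FALSE
        break
      }
    }
    if (shared) return(term)
  }
  stop_tc("disjoint_lineages",
          "the lineages share no taxonomy term (disjoint lineages)")
}

# Members (sequence, species, ord) of a node: a collapsed group or an
# annotated leaf carries them in its payload; an internal node aggregates
# its leaves.
node_members <- function(node) {
  if (!is.null(node$payload)) return(node$payload$members)
  do.call(rbind, lapply(collect_leaves(node), function(lf) lf$payload$members))
}

#' Test whether two sibling nodes are collapsible
#'
#' Two siblings are collapsible iff (i) all their member sequences share
#' a common taxonomic ancestor that, in every member's lineage, lies at
#' or below (more specific than) that lineage's first stop term, and
#' (ii) the union of their member species contains no repeats, so a merge
#' never hides a gene duplication. Members whose lineage contains no stop
#' term never collapse.
#'
#' @param a,b sibling nodes of a tree prepared by [collapse_tree()], or
#'   any node carrying member payloads; a plain leaf carries a singleton.
#' @param taxonomy a `taxonomy` covering every member species.
#' @param stops character vector of stop terms.
#' @return `TRUE` or `FALSE`.
#' @export
is_collapsible <- function(a, b, taxonomy, stops) {
  mem <- rbind(node_members(a), node_members(b))
  if (anyDuplicated(mem$species) > 0L) return(FALSE)
  lineages <- lapply(mem$species, function(sp) lineage(taxonomy, sp))
  lca <- tryCatch(taxon_lca(lineages),
                  tc_disjoint_lineages = function(e) NULL)
  if (is.null(lca)) return(FALSE)
  for (lin in lineages) {
    stop_idx <- which(lin %in% stops)
    if (length(stop_idx) == 0L) return(FALSE)
    if (match(lca, lin) > stop_idx[1]) return(FALSE)
  }
  TRUE
}

#' Weighted-average branch length of merged siblings
#'
#' When siblings collapse on a phylogram, the new branch length is the
#' average of the collapsed branch lengths weighted by the number of leaf
#' nodes under each branch divided by the total leaves being collapsed:
#' sum(l_i * n_i) / sum(n_i).
#'
#' @param lengths numeric vector of branch lengths.
#' @param n_leaves integer vector (same length): leaves under each branch.
#' @return the merged branch length.
#' @examples
#' merged_edge_length(c(0.1, 0.3), c(1, 1))  # 0.2
#' merged_edge_length(c(0.1, 0.3), c(1, 3))  # 0.25
#' @export
merged_edge_length <- function(lengths, n_leaves) {
  stopifnot(length(lengths) == length(n_leaves), all(n_leaves >= 1))
  if (anyNA(lengths)) {
    stop_tc("lengths_required",
            "cannot merge branches: a collapsed branch is missing its length")
  }
  sum(lengths * n_leaves) / sum(n_leaves)
}

#' Collapse an only child into its parent
#'
#' When a merge leaves a collapsed node with no remaining siblings, the
#' node replaces its parent and the resulting branch length is the sum of
#' the two branch lengths (child keeps its name and group membership).
#'
#' @param parent a node with exactly one child.
#' @return the promoted child node.
#' @export
merge_with_parent <- function(parent) {
  if (length(parent$children) != 1L) {
    stop_tc("contract",
            "merge_with_parent applies only to a node with exactly one child")
  }
  child <- parent$children[[1]]
  child$edge_length <- sum_lengths(parent$edge_length, child$edge_length)
  child
}

sum_lengths <- function(a, b) {
  if (is.na(a)) return(b)
  if (is.na(b)) return(a)
  a + b
}

#' Options for [collapse_tree()]
#'
#' @param stops character vector of stop terms (non-empty).
#' @param flatten_first flatten the taxonomy with the stop terms before
#'   collapsing, so groups are named by the stop term itself.
#' @param output_mode `"cladogram"` or `"phylogram"`; phylogram requires
#'   the input tree to carry branch lengths.
#' @return a `collapse_options` list.
#' @export
collapse_options <- function(stops, flatten_first = FALSE,
                             output_mode = c("cladogram", "phylogram")) {
  stops <- unique(stops[nzchar(stops)])
  if (length(stops) == 0L) {
    stop_tc("configuration", "collapsing requires a non-empty stop-term set")
  }
  structure(list(stops = stops, flatten_first = isTRUE(flatten_first),
                 output_mode = match.arg(output_mode)),
            class = "collapse_options")
}

#' Collapse a gene tree by taxonomy
#'
#' Iteratively merges collapsible sibling clades (see [is_collapsible()])
#' in deterministic post-order, left to right, retesting sibling pairs
#' after every merge until no pair is collapsible. Each merge replaces
#' two siblings by one collapsed node; a collapsed node left without
#' siblings is promoted into its parent with summed branch lengths.
#' Collapsed nodes are named `<ancestor>_<index>_<count>` where
#' `<ancestor>` is the lowest common taxonomic ancestor of the group's
#' members (a stop term itself when `flatten_first` is set), `<index>` an
#' auto-incremental group index (creation order, starting at 1) and
#' `<count>` the number of original sequences in the group.
#'
#' @param tree a `collapser_tree`.
#' @param mapping data.frame (`sequence`, `species`) covering every leaf.
#' @param taxonomy a `taxonomy` covering every mapped species.
#' @param opts a [collapse_options()] object.
#' @return an object of class `collapse_result` with elements `tree` (the
#'   collapsed `collapser_tree`), `groups` (list of collapsed groups:
#'   `name`, `ancestor_term`, `group_index`, `n_leaves`, `members`),
#'   `taxonomy` (the taxonomy actually used, flattened if requested),
#'   `warnings` (character), and `n_input_leaves`.
#' @export
collapse_tree <- function(tree, mapping, taxonomy, opts) {
  stopifnot(inherits(tree, "collapser_tree"), inherits(opts, "collapse_options"))
  if (opts$output_mode == "phylogram" && !tree$has_lengths) {
    stop_tc("lengths_required",
            "phylogram output requested but the input phylogenetic tree must include branch lengths")
  }

  warnings <- character(0)
  tax <- taxonomy
  if (opts$flatten_first) {
    tax <- withCallingHandlers(
      flatten_taxonomy(taxonomy, opts$stops),
      tc_warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  leaves <- leaf_labels(tree)
  missing_map <- leaves[vapply(leaves, function(lf) is.null(mapping_lookup(mapping, lf)),
                               logical(1))]
  if (length(missing_map) > 0L) {
    stop_tc("unknown_species",
            sprintf("tree leaves without a species mapping: %s",
                    paste(missing_map, collapse = ", ")))
  }
  spp <- unique(mapping$species[match(leaves, mapping$sequence)])
  missing_tax <- setdiff(spp, names(tax))
  if (length(missing_tax) > 0L) {
    stop_tc("unknown_species",
            sprintf("species without a lineage in the taxonomy: %s",
                    paste(missing_tax, collapse = ", ")))
  }

  ctx <- new.env(parent = emptyenv())
  ctx$taxonomy <- tax
  ctx$stops <- opts$stops
  ctx$use_lengths <- tree$has_lengths
  ctx$counter <- 0L
  ctx$warnings <- warnings

  root <- annotate_leaves(tree$root, mapping, new.env(parent = emptyenv()))
  root <- collapse_rec(root, ctx)

  # consecutive final indices, preserving creation order
  groups <- extract_groups(root)
  if (length(groups) > 0L) {
    ord <- order(vapply(groups, function(g) g$group_index, integer(1)))
    groups <- groups[ord]
    remap <- stats::setNames(seq_along(groups),
                             vapply(groups, function(g) g$group_index, integer(1)))
    root <- renumber_groups(root, remap)
    groups <- lapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      g$group_index <- i
      g$name <- group_display_name(g$ancestor_term, i, g$n_leaves)
      g
    })
  }
  root <- strip_payload_labels(root)

  out_tree <- new_tree(root)
  res <- structure(
    list(tree = out_tree, groups = groups, taxonomy = tax,
         warnings = ctx$warnings, n_input_leaves = length(leaves)),
    class = "collapse_result"
  )
  stopifnot(sum(vapply(groups, function(g) g$n_leaves, integer(1))) +
              sum(is.na(match(leaf_labels(out_tree),
                              vapply(groups, function(g) g$name, character(1))))) ==
              length(leaves))
  res
}

annotate_leaves <- function(node, mapping, counter_env) {
  if (is.null(counter_env$i)) counter_env$i <- 0L
  if (is_leaf_node(node)) {
    counter_env$i <- counter_env$i + 1L
    node$payload <- list(
      members = data.frame(sequence = node$label,
                           species = mapping_lookup(mapping, node$label),
                           ord = counter_env$i,
                           stringsAsFactors = FALSE),
      n_leaves = 1L,
      group_index = NA_integer_,
      ancestor_term = NA_character_
    )
    return(node)
  }
  node$children <- lapply(node$children, annotate_leaves,
                          mapping = mapping, counter_env = counter_env)
  node
}

is_group_node <- function(node) {
  !is.null(node$payload) && !is.na(node$payload$group_index)
}

collapse_rec <- function(node, ctx) {
  if (is_leaf_node(node)) return(node)
  node$children <- lapply(node$children, collapse_rec, ctx = ctx)

  repeat {
    pair <- find_collapsible_pair(node$children, ctx)
    if (is.null(pair)) break
    node$children <- merge_children(node$children, pair[1], pair[2], ctx)
  }

  if (length(node$children) == 1L && is_group_node(node$children[[1]])) {
    return(merge_with_parent(node))
  }
  node
}

find_collapsible_pair <- function(children, ctx) {
  k <- length(children)
  if (k < 2L) return(NULL)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (is_collapsible(children[[i]], children[[j]],
                         ctx$taxonomy, ctx$stops)) {
        return(c(i, j))
      }
    }
  }
  NULL
}

merge_children <- function(children, i, j, ctx) {
  a <- children[[i]]
  b <- children[[j]]
  mem <- rbind(node_members(a), node_members(b))
  mem <- mem[order(mem$ord), , drop = FALSE]
  lineages <- lapply(mem$species, function(sp) lineage(ctx$taxonomy, sp))
  anc <- taxon_lca(lineages)
  n_a <- nrow(node_members(a))
  n_b <- nrow(node_members(b))

  idx <- group_index_for(a, b, ctx)
  len <- if (ctx$use_lengths) {
    merged_edge_length(c(a$edge_length, b$edge_length), c(n_a, n_b))
  } else {
    NA_real_
  }
  merged <- new_node(label = NULL, edge_length = len,
                     payload = list(members = mem,
                                    n_leaves = n_a + n_b,
                                    group_index = idx,
                                    ancestor_term = anc))
  children[[i]] <- merged
  children[[j]] <- NULL
  children
}

# a fresh index for a brand-new group; a group absorbing a leaf or another
# group keeps its (earliest) existing index
group_index_for <- function(a, b, ctx) {
  ia <- if (is_group_node(a)) a$payload$group_index else NA_integer_
  ib <- if (is_group_node(b)) b$payload$group_index else NA_integer_
  if (is.na(ia) && is.na(ib)) {
    ctx$counter <- ctx$counter + 1L
    return(ctx$counter)
  }
  min(ia, ib, na.rm = TRUE)
}

group_display_name <- function(ancestor, index, n) {
  sanitize_label(sprintf("%s_%d_%d", ancestor, index, n))
}

extract_groups <- function(node) {
  if (is_leaf_node(node)) {
    if (!is_group_node(node)) return(list())
    p <- node$payload
    return(list(list(
      name = group_display_name(p$ancestor_term, p$group_index, p$n_leaves),
      ancestor_term = p$ancestor_term,
      group_index = p$group_index,
      n_leaves = p$n_leaves,
      members = p$members[, c("sequence", "species")]
    )))
  }
  out <- list()
  for (ch in node$children) out <- c(out, extract_groups(ch))
  out
}

renumber_groups <- function(node, remap) {
  if (is_group_node(node)) {
    node$payload$group_index <- unname(remap[[as.character(node$payload$group_index)]])
  }
  node$children <- lapply(node$children, renumber_groups, remap = remap)
  node
}

# turn group payloads into display labels; drop payloads everywhere
strip_payload_labels <- function(node) {
  if (is_group_node(node)) {
    p <- node$payload
    node$label <- group_display_name(p$ancestor_term, p$group_index, p$n_leaves)
  }
  node$payload <- NULL
  node$children <- lapply(node$children, strip_payload_labels)
  node
}

#' @export
print.collapse_result <- function(x, ...) {
  n_groups <- length(x$groups)
  n_grouped <- sum(vapply(x$groups, function(g) g$n_leaves, integer(1)))
  cat(sprintf("Collapsed tree: %d input sequences -> %d leaves (%d collapsed groups holding %d sequences)\n",
              x$n_input_leaves, count_leaves(x$tree), n_groups, n_grouped))
  for (g in utils::head(x$groups, 8)) {
    cat(sprintf("  %-30s %d sequences\n", g$name, g$n_leaves))
  }
  if (n_groups > 8) cat(sprintf("  ... and %d more groups\n", n_groups - 8))
  if (length(x$warnings) > 0) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' Group-membership table of a collapse result
#'
#' One row per (group, member sequence): column 1 the collapsed node
#' display name, column 2 the member sequence name. Groups appear in
#' index order and members in original leaf order. The first line is the
#' header `collapsed_node<TAB>sequence`.
#'
#' @param result a `collapse_result`.
#' @param file optional path to write the TSV to.
#' @return character vector of TSV lines (invisibly when `file` is given).
#' @export
emit_collapsed_nodes_tsv <- function(result, file = NULL) {
  stopifnot(inherits(result, "collapse_result"))
  lines <- "collapsed_node\tsequence"
  for (g in result$groups) {
    lines <- c(lines, paste(g$name, g$members$sequence, sep = "\t"))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Scan a tree for collapsible sibling pairs
#'
#' Diagnostic used to verify the fixpoint property: exhaustively tests
#' every sibling pair of the tree (using each node's member sequences)
#' and counts the collapsible ones. After [collapse_tree()] this is 0.
#'
#' @param tree a `collapser_tree`.
#' @param mapping data.frame (`sequence`, `species`).
#' @param taxonomy a `taxonomy`.
#' @param stops character vector of stop terms.
#' @param groups optional list of collapsed groups (from a
#'   `collapse_result`): leaves named like a group are given that group's
#'   member set instead of being looked up in the mapping.
#' @return integer: number of collapsible sibling pairs.
#' @export
count_collapsible_pairs <- function(tree, mapping, taxonomy, stops,
                                    groups = list()) {
  if (length(groups) > 0L) {
    extra <- do.call(rbind, lapply(groups, function(g) {
      data.frame(sequence = g$name, species = NA_character_,
                 stringsAsFactors = FALSE)
    }))
    mapping <- rbind(mapping, extra[!extra$sequence %in% mapping$sequence, ])
  }
  root <- annotate_leaves(tree$root, mapping, new.env(parent = emptyenv()))
  if (length(groups) > 0L) {
    root <- attach_group_members(root, groups)
  }
  scan_node <- function(node) {
    if (is_leaf_node(node)) return(0L)
    k <- length(node$children)
    n <- 0L
    if (k >= 2L) {
      for (i in seq_len(k - 1L)) {
        for (j in seq.int(i + 1L, k)) {
          if (is_collapsible(node$children[[i]], node$children[[j]],
                             taxonomy, stops)) {
            n <- n + 1L
          }
        }
      }
    }
    n + sum(vapply(node$children, scan_node, integer(1)))
  }
  scan_node(root)
}

attach_group_members <- function(node, groups) {
  if (is_leaf_node(node)) {
    for (g in groups) {
      if (identical(g$name, node$label)) {
        mem <- g$members
        mem$ord <- seq_len(nrow(mem))
        node$payload <- list(members = mem, n_leaves = g$n_leaves,
                             group_index = NA_integer_,
                             ancestor_term = NA_character_)
        break
      }
    }
    return(node)
  }
  node$children <- lapply(node$children, attach_group_members, groups = groups)
  node
}
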