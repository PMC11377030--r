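# Synthetic world generator and the naive reference oracle.
#
# A "world" is a random rooted binary gene tree over paralogs of
# synthetic species, together with a nested taxonomy (species < genus <
# family < order < class < root) and the sequence-to-species mapping.
# Everything is reproducible from a seed, so end-to-end tests need no
# downloads. Edge lengths are exponential with mean 0.1 — any positive
# distribution would do; this one keeps printed trees short.

#' Generate a synthetic tree + taxonomy world
#'
#' Builds a random rooted binary tree whose leaves are
#' `<species>_seq<i>` sequence names (1 to `n_paralogs_max` paralogs per
#' species), a taxonomy consistent with a random nested rank assignment,
#' and the matching sequence-to-species mapping. The same seed always
#' yields the identical world.
#'
#' @param n_species number of species (>= 1).
#' @param n_paralogs_max maximum paralogs (gene copies) per species; the
#'   actual count per species is uniform on 1..n_paralogs_max.
#' @param ranks named integer vector: average number of children per
#'   taxonomy level, from the species level upward. The default groups
#'   roughly 3 species per genus, 3 genera per family, and so on.
#' @param seed integer seed.
#' @return list of class `synthetic_world`: `taxonomy`, `tree`,
#'   `mapping`, `seed`, and `rank_terms` (terms by rank, useful for
#'   drawing stop-term sets).
#' @export
generate_world <- function(n_species, n_paralogs_max = 1L,
                           ranks = c(genus = 3, family = 3, order = 3, class = 2),
                           seed = 1L) {
  stopifnot(n_species >= 1L, n_paralogs_max >= 1L, length(ranks) >= 1L)
  withr::with_seed(seed, {
    # nested rank assignment, bottom-up: each unit at one level belongs
    # to exactly one unit of the next level
    rank_names <- names(ranks)
    n_units <- integer(length(ranks))
    n_prev <- n_species
    assign_up <- list()
    for (r in seq_along(ranks)) {
      n_units[r] <- max(1L, ceiling(n_prev / ranks[[r]]))
      assign_up[[r]] <- sample.int(n_units[r], n_prev, replace = TRUE)
      n_prev <- n_units[r]
    }
    term_name <- function(rank, i) {
      sprintf("%s%02d", c(genus = "Gen", family = "Fam", order = "Ord",
                          class = "Cls")[rank], i)
    }
    rank_terms <- lapply(seq_along(ranks), function(r) {
      vapply(seq_len(n_units[r]), function(i) term_name(rank_names[r], i),
             character(1))
    })
    names(rank_terms) <- rank_names

    taxonomy <- list()
    species <- character(n_species)
    for (s in seq_len(n_species)) {
      path <- integer(length(ranks))
      cur <- s
      for (r in seq_along(ranks)) {
        cur <- assign_up[[r]][cur]
        path[r] <- cur
      }
      genus <- rank_terms[[1]][path[1]]
      sp <- sprintf("%s_sp%02d", genus, s)
      species[s] <- sp
      taxonomy[[sp]] <- c(sp,
                          vapply(seq_along(ranks),
                                 function(r) rank_terms[[r]][path[r]],
                                 character(1)),
                          "Eukaryota")
    }
    taxonomy <- structure(taxonomy, class = "taxonomy")

    n_par <- sample.int(n_paralogs_max, n_species, replace = TRUE)
    seqs <- unlist(lapply(seq_len(n_species), function(s) {
      sprintf("%s_seq%d", species[s], seq_len(n_par[s]))
    }))
    seq_species <- rep(species, times = n_par)
    mapping <- data.frame(sequence = seqs, species = seq_species,
                          stringsAsFactors = FALSE)

    # random binary topology: repeatedly join two random subtrees
    pool <- lapply(seqs, function(sq) {
      new_node(label = sq, edge_length = stats::rexp(1, rate = 10))
    })
    while (length(pool) > 1L) {
      pick <- sample.int(length(pool), 2L)
      joined <- new_node(edge_length = stats::rexp(1, rate = 10),
                         children = pool[sort(pick)])
      pool <- c(pool[-sort(pick)], list(joined))
    }
    root <- pool[[1]]
    root$edge_length <- NA_real_
    tree <- new_tree(root)

    structure(list(taxonomy = taxonomy, tree = tree, mapping = mapping,
                   seed = seed, rank_terms = rank_terms),
              class = "synthetic_world")
  })
}

#' Write a synthetic world to files
#'
#' Persists the world's tree (Newick phylogram), taxonomy and mapping in
#' the exact external file formats, so command-line tests can run
#' end-to-end on them.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return named list of the written paths (`tree`, `taxonomy`,
#'   `mapping`).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(tree = file.path(dir, "tree.nwk"),
                taxonomy = file.path(dir, "taxonomy.txt"),
                mapping = file.path(dir, "mapping.tsv"))
  write_tree(world$tree, mode = "phylogram", file = paths$tree)
  serialize_taxonomy(world$taxonomy, file = paths$taxonomy)
  serialize_sequence_mapping(world$mapping, file = paths$mapping)
  paths
}

#' Naive reference collapser (oracle)
#'
#' A deliberately simple re-implementation of the collapsing procedure
#' used as an independent check of [collapse_tree()]: it works on a flat
#' parent-pointer table, recomputes collapsibility from first principles
#' (brute-force term intersection), and rescans *all* sibling pairs of
#' the whole tree after every single merge, taking nodes in lexicographic
#' id order. It tracks group membership only (no branch lengths, no
#' naming) and returns the partition of collapsed sequences.
#'
#' @param world a `synthetic_world` (or a list with `tree`, `mapping`,
#'   `taxonomy`).
#' @param stops character vector of stop terms (non-empty).
#' @return list of character vectors: the sorted member-sequence sets of
#'   the collapsed groups, ordered lexicographically.
#' @export
naive_collapse_oracle <- function(world, stops) {
  stops <- unique(stops[nzchar(stops)])
  if (length(stops) == 0L) {
    stop_tc("configuration", "collapsing requires a non-empty stop-term set")
  }
  tax <- world$taxonomy
  mapping <- world$mapping

  # flat node table built by an id-assigning walk
  nodes <- list()
  add_node <- function(node, parent_id) {
    id <- sprintf("n%04d", length(nodes) + 1L)
    rec <- list(id = id, parent = parent_id, children = character(0),
                seqs = if (is_leaf_node(node)) node$label else character(0),
                merged = FALSE, alive = TRUE)
    nodes[[id]] <<- rec
    for (ch in node$children) {
      cid <- add_node(ch, id)
      nodes[[id]]$children <<- c(nodes[[id]]$children, cid)
    }
    id
  }
  root_id <- add_node(world$tree$root, NA_character_)

  members_of <- function(id) {
    rec <- nodes[[id]]
    if (length(rec$children) == 0L) return(rec$seqs)
    unlist(lapply(rec$children, members_of))
  }
  first_stop_pos <- function(terms) {
    hit <- which(terms %in% stops)
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }
  pair_collapsible <- function(id_a, id_b) {
    seqs <- c(members_of(id_a), members_of(id_b))
    spp <- mapping$species[match(seqs, mapping$sequence)]
    if (anyDuplicated(spp) > 0L) return(FALSE)
    lins <- lapply(spp, function(sp) tax[[sp]])
    if (any(vapply(lins, is.null, logical(1)))) return(FALSE)
    shared <- Reduce(intersect, lins)
    if (length(shared) == 0L) return(FALSE)
    # LCA = shared term with the smallest index in the first lineage
    lca <- lins[[1]][min(match(shared, lins[[1]]))]
    for (lin in lins) {
      sp_pos <- first_stop_pos(lin)
      if (is.na(sp_pos) || match(lca, lin) > sp_pos) return(FALSE)
    }
    TRUE
  }

  repeat {
    internal <- sort(names(nodes)[vapply(names(nodes), function(id) {
      nodes[[id]]$alive && length(nodes[[id]]$children) >= 2L
    }, logical(1))])
    hit <- NULL
    for (id in internal) {
      kids <- nodes[[id]]$children
      for (i in seq_len(length(kids) - 1L)) {
        for (j in seq.int(i + 1L, length(kids))) {
          if (pair_collapsible(kids[i], kids[j])) {
            hit <- list(parent = id, a = kids[i], b = kids[j], pos = i)
            break
          }
        }
        if (!is.null(hit)) break
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break

    # merge: replace the two children by one merged leaf-like node
    new_id <- sprintf("n%04d", length(nodes) + 1L)
    nodes[[new_id]] <- list(id = new_id, parent = hit$parent,
                            children = character(0),
                            seqs = c(members_of(hit$a), members_of(hit$b)),
                            merged = TRUE, alive = TRUE)
    kids <- nodes[[hit$parent]]$children
    kids[hit$pos] <- new_id
    kids <- kids[kids != hit$b]
    nodes[[hit$parent]]$children <- kids
    kill_subtree <- function(id) {
      nodes[[id]]$alive <<- FALSE
      for (cid in nodes[[id]]$children) kill_subtree(cid)
    }
    kill_subtree(hit$a)
    kill_subtree(hit$b)

    # only-child promotion so the merged node regains siblings above
    pid <- hit$parent
    while (!is.na(pid) && length(nodes[[pid]]$children) == 1L &&
           nodes[[nodes[[pid]]$children[1]]]$merged) {
      child <- nodes[[pid]]$children[1]
      gp <- nodes[[pid]]$parent
      nodes[[child]]$parent <- gp
      if (!is.na(gp)) {
        gkids <- nodes[[gp]]$children
        gkids[gkids == pid] <- child
        nodes[[gp]]$children <- gkids
      } else {
        root_id <- child
      }
      nodes[[pid]]$alive <- FALSE
      pid <- gp
    }
  }

  groups <- lapply(names(nodes)[vapply(names(nodes), function(id) {
    nodes[[id]]$alive && nodes[[id]]$merged
  }, logical(1))], function(id) sort(nodes[[id]]$seqs))
  groups[order(vapply(groups, function(g) g[1], character(1)))]
}
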