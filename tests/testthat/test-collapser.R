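# The collapsing algorithm: LCA, collapsibility, branch-length rules,
# the fixpoint iteration, and the group-membership table.

test_that("taxon_lca finds the most specific shared term", {
  tax <- diptera_taxonomy()
  expect_equal(taxon_lca(list(lineage(tax, "Drosophila_melanogaster"),
                              lineage(tax, "Bactrocera_latifrons"))),
               "Acalyptratae")
  lin <- lineage(tax, "Drosophila_melanogaster")
  expect_equal(taxon_lca(list(lin, lin)), "Drosophila_melanogaster")
  expect_error(taxon_lca(list(c("A", "B"), c("C", "D"))),
               class = "tc_disjoint_lineages")

  # brute-force oracle: intersection term with minimal index in lineage 1
  withr::with_seed(99, {
    pool <- sprintf("t%02d", 1:20)
    for (i in 1:25) {
      l1 <- c(sample(pool, 6), "Eukaryota")
      l2 <- c(sample(pool, 6), "Eukaryota")
      l3 <- c(sample(pool, 6), "Eukaryota")
      shared <- Reduce(intersect, list(l1, l2, l3))
      brute <- l1[min(match(shared, l1))]
      expect_equal(taxon_lca(list(l1, l2, l3)), brute)
    }
  })
})

test_that("collapsibility follows the stop-term and species-duplication rules", {
  tax <- diptera_taxonomy()
  tr <- diptera_tree()
  map <- diptera_mapping()
  prep <- treecollapse:::annotate_leaves(tr$root, map,
                                         new.env(parent = emptyenv()))
  a <- prep$children[[1]]
  b <- prep$children[[2]]

  # family stop terms: shared ancestor Acalyptratae is ABOVE both families
  expect_false(is_collapsible(a, b, tax, c("Drosophilidae", "Tephritidae")))
  # order stop term: Acalyptratae is below Diptera
  expect_true(is_collapsible(a, b, tax, "Diptera"))
  # the stop term itself shared counts as collapsible
  expect_true(is_collapsible(a, b, tax, "Acalyptratae"))

  # same species never collapses, whatever the stops
  tr2 <- parse_tree("(Drosophila_melanogaster_seq1,Drosophila_melanogaster_seq2);")
  map2 <- data.frame(sequence = leaf_labels(tr2),
                     species = rep("Drosophila_melanogaster", 2))
  prep2 <- treecollapse:::annotate_leaves(tr2$root, map2,
                                          new.env(parent = emptyenv()))
  expect_false(is_collapsible(prep2$children[[1]], prep2$children[[2]],
                              tax, "Eukaryota"))

  # species absent from the taxonomy is an error naming it
  map3 <- map
  map3$species[1] <- "Musca_domestica"
  prep3 <- treecollapse:::annotate_leaves(tr$root, map3,
                                          new.env(parent = emptyenv()))
  err <- tryCatch(is_collapsible(prep3$children[[1]], prep3$children[[2]],
                                 tax, "Diptera"),
                  error = identity)
  expect_s3_class(err, "tc_unknown_species")
  expect_match(conditionMessage(err), "Musca_domestica")
})

test_that("merged edge lengths are the leaf-weighted average and stay bounded", {
  expect_equal(merged_edge_length(c(0.1, 0.3), c(1, 1)), 0.2)
  expect_equal(merged_edge_length(c(0.1, 0.3), c(1, 3)), 0.25)
  expect_equal(merged_edge_length(0.42, 5), 0.42)
  expect_error(merged_edge_length(c(0.1, NA), c(1, 1)),
               class = "tc_lengths_required")

  withr::with_seed(4, {
    for (i in 1:50) {
      k <- sample(2:5, 1)
      l <- runif(k)
      n <- sample(1:6, k, replace = TRUE)
      m <- merged_edge_length(l, n)
      expect_gte(m, min(l))
      expect_lte(m, max(l))
    }
  })
})

test_that("an only child collapses into its parent with summed lengths", {
  child <- list(label = "G", edge_length = 0.2, children = list(),
                payload = list(members = data.frame(sequence = "s", species = "x",
                                                    ord = 1L),
                               n_leaves = 1L, group_index = 1L,
                               ancestor_term = "F"))
  parent <- list(label = NULL, edge_length = 0.3, children = list(child),
                 payload = NULL)
  out <- merge_with_parent(parent)
  expect_equal(out$edge_length, 0.5)
  expect_equal(out$label, "G")

  parent$children <- list(child, child)
  expect_error(merge_with_parent(parent), class = "tc_contract")

  # lengthless path: node promoted, no length invented
  p2 <- list(label = NULL, edge_length = NA_real_, children = list(
    list(label = "G", edge_length = NA_real_, children = list(), payload = NULL)),
    payload = NULL)
  expect_true(is.na(merge_with_parent(p2)$edge_length))
})

test_that("the two-species worked example collapses exactly as documented", {
  tax <- diptera_taxonomy()
  tr <- diptera_tree()
  map <- diptera_mapping()

  # family stops: not collapsible, tree unchanged, zero groups
  r1 <- collapse_tree(tr, map, tax,
                      collapse_options(c("Drosophilidae", "Tephritidae"),
                                       output_mode = "phylogram"))
  expect_length(r1$groups, 0L)
  expect_identical(write_tree(r1$tree, "phylogram"), write_tree(tr, "phylogram"))

  # order stop: one collapsed leaf named after the LCA, holding both
  r2 <- collapse_tree(tr, map, tax,
                      collapse_options("Diptera", output_mode = "phylogram"))
  expect_length(r2$groups, 1L)
  g <- r2$groups[[1]]
  expect_equal(g$ancestor_term, "Acalyptratae")
  expect_equal(g$n_leaves, 2L)
  expect_equal(g$name, "Acalyptratae_1_2")
  expect_equal(leaf_labels(r2$tree), "Acalyptratae_1_2")
  # weighted mean of 0.1 and 0.2 (equal weights), promoted to the root
  expect_equal(pairwise_leaf_depths(r2$tree)[["Acalyptratae_1_2"]], 0.15)
})

test_that("cascading merges: caterpillar of one family becomes a single group", {
  tax <- parse_taxonomy(c("A_a;Fam;Ord", "B_b;Fam;Ord",
                          "C_c;Fam;Ord", "D_d;Fam;Ord"))
  tr <- parse_tree("(((A_a_1:0.1,B_b_1:0.2):0.3,C_c_1:0.4):0.5,D_d_1:0.6);")
  map <- data.frame(sequence = leaf_labels(tr),
                    species = c("A_a", "B_b", "C_c", "D_d"))
  r <- collapse_tree(tr, map, tax, collapse_options("Fam", "phylogram"))
  expect_length(r$groups, 1L)
  expect_equal(r$groups[[1]]$name, "Fam_1_4")
  expect_setequal(r$groups[[1]]$members$sequence, map$sequence)
  expect_equal(leaf_labels(r$tree), "Fam_1_4")

  # naive oracle computed the same partition
  o <- naive_collapse_oracle(list(tree = tr, mapping = map, taxonomy = tax),
                             "Fam")
  expect_identical(o, list(sort(map$sequence)))
})

test_that("successive only-child promotions accumulate the full path length", {
  tax <- parse_taxonomy(c("A_a;Fam;Ord", "B_b;Fam;Ord", "C_c;Fam2;Ord"))
  # unary node above the collapsing cherry forces two promotions
  tr <- parse_tree("(((A_a_1:0.1,B_b_1:0.3):0.25):0.4,C_c_1:1.0);")
  map <- data.frame(sequence = leaf_labels(tr),
                    species = c("A_a", "B_b", "C_c"))
  r <- collapse_tree(tr, map, tax, collapse_options("Fam", "phylogram"))
  expect_length(r$groups, 1L)
  # mean(0.1, 0.3) + 0.25 + 0.4
  expect_equal(r$tree$root$children[[1]]$edge_length, 0.85)
})

test_that("a tree whose leaves are all one species never collapses", {
  tax <- parse_taxonomy("A_a;Fam;Ord;Eukaryota")
  tr <- parse_tree("((A_a_1,A_a_2),(A_a_3,A_a_4));")
  map <- data.frame(sequence = leaf_labels(tr), species = rep("A_a", 4))
  for (stops in list("Fam", "Ord", "Eukaryota")) {
    r <- collapse_tree(tr, map, tax, collapse_options(stops))
    expect_length(r$groups, 0L)
    expect_identical(write_tree(r$tree), write_tree(tr))
  }
})

test_that("polytomies collapse deterministically", {
  tax <- parse_taxonomy(c("A_a;Fam;Ord", "B_b;Fam;Ord", "C_c;Fam;Ord"))
  tr <- parse_tree("(A_a_1,B_b_1,C_c_1);")
  map <- data.frame(sequence = leaf_labels(tr),
                    species = c("A_a", "B_b", "C_c"))
  r <- collapse_tree(tr, map, tax, collapse_options("Fam"))
  expect_length(r$groups, 1L)
  expect_equal(r$groups[[1]]$n_leaves, 3L)
  expect_equal(leaf_labels(r$tree), "Fam_1_3")
})

test_that("the group table maps every member in order, with a header", {
  tax <- diptera_taxonomy()
  r <- collapse_tree(diptera_tree(), diptera_mapping(), tax,
                     collapse_options("Diptera"))
  tsv <- emit_collapsed_nodes_tsv(r)
  expect_equal(tsv[1], "collapsed_node\tsequence")
  expect_equal(tsv[-1],
               c("Acalyptratae_1_2\tBactrocera_latifrons_seq1",
                 "Acalyptratae_1_2\tDrosophila_melanogaster_seq1"))

  r0 <- collapse_tree(diptera_tree(), diptera_mapping(), tax,
                      collapse_options(c("Drosophilidae", "Tephritidae")))
  expect_equal(emit_collapsed_nodes_tsv(r0), "collapsed_node\tsequence")

  for (seed in 1:5) {
    w <- generate_world(n_species = 9, n_paralogs_max = 3, seed = seed)
    rw <- collapse_tree(w$tree, w$mapping, w$taxonomy,
                        collapse_options(world_stops(w, "family")))
    tsvw <- emit_collapsed_nodes_tsv(rw)
    expect_length(tsvw,
                  1L + sum(vapply(rw$groups, function(g) g$n_leaves, integer(1))))
  }
})

test_that("collapse invariants hold on random worlds", {
  for (seed in 1:20) {
    w <- generate_world(n_species = 2 + (seed %% 10), n_paralogs_max = 3,
                        seed = seed)
    rank <- c("family", "order", "class")[1 + (seed %% 3)]
    stops <- world_stops(w, rank)
    r <- collapse_tree(w$tree, w$mapping, w$taxonomy,
                       collapse_options(stops, output_mode = "phylogram"))

    # conservation: groups + surviving original leaves == input leaves
    grouped <- sum(vapply(r$groups, function(g) g$n_leaves, integer(1)))
    survivors <- sum(leaf_labels(r$tree) %in% w$mapping$sequence)
    expect_equal(grouped + survivors, count_leaves(w$tree))

    # duplication preservation: no group holds one species twice
    for (g in r$groups) {
      expect_false(any(duplicated(g$members$species)))
      expect_equal(g$n_leaves, nrow(g$members))
    }

    # group indices are consecutive from 1
    expect_equal(vapply(r$groups, function(g) g$group_index, integer(1)),
                 seq_along(r$groups))

    # fixpoint: the exhaustive post-hoc scan finds nothing collapsible
    expect_equal(count_collapsible_pairs(r$tree, w$mapping, w$taxonomy,
                                         stops, groups = r$groups), 0L)

    # untouched leaves keep their edge lengths
    d0 <- pairwise_leaf_depths(w$tree)
    d1 <- pairwise_leaf_depths(r$tree)
    keep <- intersect(names(d0), names(d1))
    expect_equal(d1[keep], d0[keep], tolerance = 1e-12)
  }
})

test_that("flattening first is equivalent except groups take stop-term names", {
  for (seed in 1:10) {
    w <- generate_world(n_species = 3 + (seed %% 8), n_paralogs_max = 2,
                        seed = 100 + seed)
    stops <- world_stops(w, "family")
    r_flat <- collapse_tree(w$tree, w$mapping, w$taxonomy,
                            collapse_options(stops, flatten_first = TRUE))
    r_pre <- collapse_tree(w$tree, w$mapping,
                           flatten_taxonomy(w$taxonomy, stops),
                           collapse_options(stops, flatten_first = FALSE))
    r_plain <- collapse_tree(w$tree, w$mapping, w$taxonomy,
                             collapse_options(stops, flatten_first = FALSE))
    expect_identical(group_partition(r_flat), group_partition(r_pre))
    expect_identical(group_partition(r_flat), group_partition(r_plain))
    expect_true(all(vapply(r_flat$groups,
                           function(g) g$ancestor_term %in% stops, logical(1))))
  }
})

test_that("collapsing is deterministic: identical reruns, byte for byte", {
  w <- generate_world(n_species = 10, n_paralogs_max = 3, seed = 77)
  stops <- world_stops(w, "family")
  run <- function() {
    r <- collapse_tree(w$tree, w$mapping, w$taxonomy,
                       collapse_options(stops, output_mode = "phylogram"))
    c(write_tree(r$tree, "phylogram"), emit_collapsed_nodes_tsv(r))
  }
  expect_identical(run(), run())
})
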