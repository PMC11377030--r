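# Shared fixtures: the two-species Diptera example used throughout the
# documentation, and small utilities for comparing group partitions.

diptera_taxonomy_lines <- function() {
  c("Bactrocera_latifrons;Tephritidae;Acalyptratae;Schizophora;Brachycera;Diptera;Eukaryota",
    "Drosophila_melanogaster;Drosophilidae;Acalyptratae;Schizophora;Brachycera;Diptera;Eukaryota")
}

diptera_taxonomy <- function() parse_taxonomy(diptera_taxonomy_lines())

diptera_tree <- function() {
  parse_tree("(Bactrocera_latifrons_seq1:0.1,Drosophila_melanogaster_seq1:0.2);")
}

diptera_mapping <- function() {
  data.frame(
    sequence = c("Bactrocera_latifrons_seq1", "Drosophila_melanogaster_seq1"),
    species = c("Bactrocera_latifrons", "Drosophila_melanogaster"),
    stringsAsFactors = FALSE
  )
}

# normalized partition (set of sorted member-sequence sets) of a result
group_partition <- function(result) {
  sets <- lapply(result$groups, function(g) sort(g$members$sequence))
  sets[order(vapply(sets, function(s) s[1], character(1)))]
}

# stop-term set for a generated world: all terms of one rank
world_stops <- function(world, rank) world$rank_terms[[rank]]

# named vector of root-to-leaf path lengths, computed by plain recursion
pairwise_leaf_depths <- function(tree) {
  depths <- c()
  walk <- function(node, acc) {
    len <- if (is.na(node$edge_length)) 0 else node$edge_length
    acc <- acc + len
    if (length(node$children) == 0L) {
      depths[[node$label]] <<- acc
    } else {
      for (ch in node$children) walk(ch, acc)
    }
  }
  walk(tree$root, 0)
  unlist(depths)
}
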