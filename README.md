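# treecollapse

Taxonomy-guided collapsing of phylogenetic gene trees.

Gene-family trees built from hundreds or thousands of coding sequences
are hard to visualize and interpret, yet much of their structure just
recapitulates the species tree. `treecollapse` collapses clades of a
rooted gene tree according to a taxonomy and a user-chosen set of **stop
terms** (family or order names, for instance), while preserving every
within-species gene duplication, so the collapsed tree still shows the
minimal set of sequences needed to recapitulate the gene family's
history at that taxonomic level. It is aimed at molecular evolution
researchers summarizing large Newick/NEXUS gene trees before detailed
reanalysis.

## The rule

Each species has a lineage `L(s) = (s, t_1, t_2, ..., t_k)`, ordered
most-specific-first. Two sibling nodes *a*, *b* with member sequences
`M = M(a) ∪ M(b)` are **collapsible** iff

1. `lca(M)` — the most specific term present in every member's lineage —
   satisfies `idx(lca(M)) ≤ idx(first stop term)` in *every* member's
   lineage (the shared ancestor is the stop term or below it), and
2. no species occurs twice in `M` (paralogs never merge, so all
   duplication signal survives).

Collapsible siblings are merged bottom-up, deterministically, until no
pair remains (a fixpoint). A merged node is named
`<ancestor>_<index>_<count>` (LCA term, auto-incremental index, number
of sequences). On a phylogram its branch length is the leaf-weighted
average `Σ l_i·n_i / Σ n_i` of the merged branches; a merged node left
without siblings is promoted into its parent with summed branch lengths.
A companion TSV maps every collapsed node to its member sequences.

## Worked example

Two fly sequences and a simplified taxonomy:

```r
library(treecollapse)

taxonomy <- parse_taxonomy(c(
  "Bactrocera_latifrons;Tephritidae;Acalyptratae;Schizophora;Brachycera;Diptera;Eukaryota",
  "Drosophila_melanogaster;Drosophilidae;Acalyptratae;Schizophora;Brachycera;Diptera;Eukaryota"))
tree <- parse_tree("(Bactrocera_latifrons_seq1:0.1,Drosophila_melanogaster_seq1:0.2);")
mapping <- data.frame(
  sequence = c("Bactrocera_latifrons_seq1", "Drosophila_melanogaster_seq1"),
  species  = c("Bactrocera_latifrons", "Drosophila_melanogaster"))

r <- collapse_tree(tree, mapping, taxonomy,
                   collapse_options("Diptera", output_mode = "phylogram"))
r
#> Collapsed tree: 2 input sequences -> 1 leaves (1 collapsed groups holding 2 sequences)
#>   Acalyptratae_1_2               2 sequences
write_tree(r$tree, "phylogram")
#> [1] "Acalyptratae_1_2:0.15;"
emit_collapsed_nodes_tsv(r)
#> [1] "collapsed_node\tsequence"
#> [2] "Acalyptratae_1_2\tBactrocera_latifrons_seq1"
#> [3] "Acalyptratae_1_2\tDrosophila_melanogaster_seq1"
```

With the order Diptera as the stop term the two sequences collapse into
one node named after their lowest common taxonomic ancestor,
`Acalyptratae`; the suffix `_1_2` is the group index and the number of
sequences it holds, and `0.15` is the equal-weight average of the two
branch lengths. With the stop terms `Drosophilidae` and `Tephritidae`
(their families) instead, the shared ancestor sits *above* both stop
terms and the tree is returned unchanged.

## Command line

A thin wrapper over the same functions is installed under
`exec/collapse-tree`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","collapse-tree",package="treecollapse"))')" \
  --input tree.nwk --taxonomy taxonomy.txt --sequence-mapping mapping.tsv \
  --taxonomy-stop-terms stops.txt --output collapsed.nwk --output-type phylogram
```

Flags mirror the function arguments (`--input-format` for NEXUS input,
`--flatten-taxonomy-with-stop-terms` to label groups by the stop terms
themselves, `--fetch-taxonomy` for opt-in NCBI lineage lookup). Missing
mapping/taxonomy inputs are inferred from sequence-name prefixes and
persisted as `.sequence_to_species_mapping` / `.taxonomy` side files;
without a stop-terms file a bundled family-name snapshot is used. Exit
codes are documented in `--help`; reruns are byte-identical.

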