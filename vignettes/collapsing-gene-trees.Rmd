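---
title: "Collapsing gene trees with taxonomic stop terms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsing gene trees with taxonomic stop terms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treecollapse)
```

## The problem

Gene-family phylogenies built from hundreds or thousands of coding
sequences are hard to read, yet most of their structure is redundant for
the question being asked: within a family or order, many leaves simply
recapitulate the species tree. What a reader needs to keep is the
*duplication signal* — every case where one species contributes more than
one sequence to a clade — while clades that contain at most one sequence
per species can be summarized by a single labelled branch.

`treecollapse` automates this: it collapses clades of a rooted gene tree
guided by a taxonomy and a set of user-chosen **stop terms** (taxonomy
terms, typically family or order names, that bound how far collapsing may
reach), and emits a collapsed Newick tree plus a TSV table mapping every
collapsed node to its member sequences.

## The collapsing rule

Every species has a **lineage**: an ordered list of taxonomy terms, most
specific first — the species itself, then its genus, family, order, and
so on. Two sibling nodes of the tree are *collapsible* iff

1. the **lowest common ancestor (LCA)** of all their member sequences —
   the most specific term present in every member's lineage — lies, in
   every member's lineage, at or below (i.e. no more general than) that
   lineage's first stop term; and
2. merging them would not put two sequences of the **same species** into
   one group.

Rule 2 is what preserves the duplication signal: two paralogs of one
species can never disappear into the same collapsed node, so every gene
duplication visible in the input remains visible in the output.

Collapsing iterates to a fixpoint. Merging runs in deterministic
post-order, left to right; at each internal node all sibling pairs are
retested after every merge until none is collapsible. When a merge leaves
a collapsed node with no siblings, the node is promoted into its parent
(it replaces the parent, and on a phylogram the two branch lengths are
summed), which lets collapsing cascade upward. Because each merge removes
at least one node, termination is guaranteed.

On a phylogram, the branch length of a merged node is the average of the
merged branch lengths weighted by the number of leaves under each branch:
`sum(l_i * n_i) / sum(n_i)`. The merged length therefore always lies
between the shortest and longest of its parts. Successive merges fold
this rule pairwise, using the current branch lengths and current leaf
counts of the two siblings being merged; this matches the per-merge
statement of the rule. An alternative reading — recomputing each merged
length from the original leaf branches — would give different interior
averages; we use the pairwise fold because it is the only interpretation
that needs no information beyond the two branches actually being merged.

Collapsed nodes are named `<ancestor>_<index>_<count>`: the LCA term of
the group's members, an auto-incremental group index (creation order,
starting at 1), and the number of original sequences in the group.
When two existing groups merge, the merged group keeps the earlier
index and its ancestor is recomputed as the LCA over *all* member
lineages (string ancestors lose lineage context); after the fixpoint
the surviving indices are renumbered consecutively, preserving creation
order.

## A worked example

Two sequences from two dipteran flies, with a simplified taxonomy:

```{r}
taxonomy <- parse_taxonomy(c(
  "Bactrocera_latifrons;Tephritidae;Acalyptratae;Schizophora;Brachycera;Diptera;Eukaryota",
  "Drosophila_melanogaster;Drosophilidae;Acalyptratae;Schizophora;Brachycera;Diptera;Eukaryota"))
tree <- parse_tree("(Bactrocera_latifrons_seq1:0.1,Drosophila_melanogaster_seq1:0.2);")
mapping <- data.frame(
  sequence = c("Bactrocera_latifrons_seq1", "Drosophila_melanogaster_seq1"),
  species  = c("Bactrocera_latifrons", "Drosophila_melanogaster"))
```

With the two *families* as stop terms, the sequences share no ancestor at
or below a stop term, so nothing collapses. With the *order* Diptera as
the stop term they do collapse, and the new node is named after the LCA,
`Acalyptratae`:

```{r}
r <- collapse_tree(tree, mapping, taxonomy,
                   collapse_options("Diptera", output_mode = "phylogram"))
write_tree(r$tree, "phylogram")
emit_collapsed_nodes_tsv(r)
```

The merged branch length 0.15 is the equal-weight average of 0.1 and 0.2
(one leaf under each branch), and the lone collapsed node has been
promoted to the root.

### Flattening

Sometimes the *stop terms themselves* are the labels one wants (collapse
at the family level and read family names off the tree). Flattening
reduces every lineage to the pair (species, first stop term):

```{r}
serialize_taxonomy(flatten_taxonomy(taxonomy, c("Drosophilidae", "Tephritidae")))
```

Collapsing after flattening produces the same group membership as
collapsing with the full taxonomy (a property the test suite asserts on
random inputs) — only the group names change from LCA terms to stop
terms. Species whose lineage contains no stop term are passed through
unchanged with a warning and are never collapsed; this is the
conservative choice, since inventing a stop level could hide
duplications. A degenerate case: if the species name itself is listed as
a stop term, its lineage is left unflattened — same-species merges are
forbidden anyway, so such a species can never collapse.

## Parameters that matter

* **Stop terms** (`collapse_options(stops = ...)`): the taxonomic level
  bounding collapsing. Family-level stops give a fine-grained summary;
  order-level stops a coarser one. When the command-line tool receives no
  stop-terms file it falls back to a bundled plain-text snapshot of
  family names (`extdata/family_stop_terms.txt`), a curated list centred
  on insect and vertebrate families — it is *not* the complete official
  family registry, and users working outside those clades should supply
  their own list.
* **Output mode**: `cladogram` (default; all branch lengths dropped,
  lengthless inputs fully supported) or `phylogram` (every branch length
  emitted; requires lengths on input, otherwise an explicit error).
* **Flattening** (`flatten_first`): see above.

## Input handling and numerical choices

* Newick and NEXUS (TREES block, with optional TRANSLATE table,
  `[&R]`/`[&U]` markers read and ignored) are parsed natively; trees are
  treated as rooted exactly as given. NeXML/PhyloXML/CDAO are recognised
  names that currently raise an "unsupported dialect" error.
* Duplicate leaf labels are a hard parse-time error (groups are keyed by
  sequence name); malformed input is reported with line and column.
* Branch lengths are kept at full double precision and printed with 12
  significant digits, so write/parse round-trips are stable to well below
  1e-9.
* Internal-node labels (e.g. support values) are preserved verbatim on
  nodes that survive; labels of collapsed nodes are discarded — support
  values for merged clades would be meaningless after merging.
* Output labels are sanitized: characters illegal in unquoted Newick are
  replaced by underscores.
* Polytomies: all sibling pairs (i < j) are tested in deterministic
  order and the first collapsible pair merges into slot i. Testing all
  pairs, not only adjacent ones, guarantees that the returned tree is a
  true fixpoint — an exhaustive post-hoc scan finds zero collapsible
  sibling pairs — for polytomous inputs too.
* The group partition is deterministic for a fixed input; we make no
  claim that it is invariant under rotations of children, and do not test
  for that.

## Species and lineage resolution

Sequence names conventionally start with the species name
(`Drosophila_melanogaster_fruit_fly_...`). Missing mapping entries are
inferred from that prefix: with a taxonomy at hand the longest
underscore-token prefix matching a known species wins (so three-token
subspecies beat their two-token prefix); otherwise the first two tokens
are used. Missing lineages can be resolved through a pluggable provider:
the offline `fixture_lineage_provider()` (a lookup in a taxonomy held in
memory; what the tests use) or the opt-in `ncbi_lineage_provider()`
(Entrez E-utilities with caching and exponential backoff; requires
network and is enabled in the CLI only via `--fetch-taxonomy`, keeping
the default pipeline fully deterministic and offline). Resolved inputs
are persisted as `<input>.taxonomy` and
`<input>.sequence_to_species_mapping` side files for reuse.

## What the synthetic worlds emulate — and what they do not

The test suite and the acceptance script draw hundreds of synthetic
"worlds": a nested random taxonomy (species < genus < family < order <
class < root, roughly 3 units per parent), 1–3 paralogs per species, and
a uniformly random rooted binary topology with exponential branch lengths
(mean 0.1 substitutions/site — any positive distribution would do; this
one keeps printed trees short). Default test sizes are 2–13 species and
at most 32 leaves per world, 200 worlds per property run, which keeps the
whole suite under a minute on one CPU.

These worlds exercise the algorithm's combinatorics (paralog placement,
stop levels at three ranks, cascaded promotions) but not features of real
data: non-uniform tree shapes, rogue taxa, misannotated sequences whose
tree position contradicts their taxonomy, rank structures with missing
intermediate ranks, or non-binary published trees. Passing the property
battery therefore demonstrates correctness of the collapsing logic, not
robustness to taxonomically inconsistent inputs — those surface as
explicit errors (unknown species, disjoint lineages) rather than wrong
groups.

A naive reference collapser (`naive_collapse_oracle()`) re-implements the
procedure from first principles on a flat parent-pointer table and
rescans every sibling pair of the whole tree after every single merge; on
every tested world its group partition equals `collapse_tree()`'s, which
is the strongest internal check the package offers.

## Known limitations

* Collapsed counts on published trees depend on the taxonomy snapshot
  used; with a present-day taxonomy they can drift from counts computed
  against older snapshots. The bundled family list is a small curated
  snapshot, not the full registry.
* No tree rooting, ladderizing or rendering; trees are consumed as
  rooted. Reconciliation and duplication/loss inference are downstream
  tools, not goals.
* Support values are not recomputed for collapsed nodes.
* NeXML/PhyloXML/CDAO input is not yet implemented.
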