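# Taxonomy, sequence-to-species mapping and stop-term inputs.
#
# File formats:
#   taxonomy   : one line per species, "species;term;term;...;term",
#                most specific first (the species itself is the first term)
#   mapping    : 2-column TSV, sequence name <TAB> species name
#   stop terms : one term per line, blank lines ignored
#
# A taxonomy is represented as a named list: names are species, each value
# a character vector of lineage terms with terms[1] == species.

#' Parse a taxonomy file
#'
#' Each non-blank line holds the lineage of one species as semicolon-
#' separated terms, most specific first: the first term is the species
#' itself, later terms are increasingly inclusive ranks (genus, family,
#' order, ...). Trailing semicolons are tolerated. Term order is part of
#' the format contract and is never auto-detected: a reversed lineage
#' would silently invert collapsibility.
#'
#' @param text character: the file content (string or vector of lines).
#' @return an object of class `taxonomy`: a named list mapping each
#'   species to its lineage (character vector).
#' @examples
#' tax <- parse_taxonomy(c(
#'   "Bactrocera_latifrons;Tephritidae;Acalyptratae;Schizophora;Brachycera;Diptera;Eukaryota",
#'   "Drosophila_melanogaster;Drosophilidae;Acalyptratae;Schizophora;Brachycera;Diptera;Eukaryota"))
#' lineage(tax, "Drosophila_melanogaster")
#' @export
parse_taxonomy <- function(text) {
  lines <- split_lines(text)
  entries <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    terms <- trimws(strsplit(line, ";", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms) | seq_along(terms) == 1L]
    if (length(terms) == 0L || !nzchar(terms[1])) {
      stop_tc("parse_error",
              sprintf("taxonomy line %d: blank species field", i))
    }
    if (anyDuplicated(terms)) {
      stop_tc("parse_error",
              sprintf("taxonomy line %d: term '%s' appears twice in the lineage of %s",
                      i, terms[duplicated(terms)][1], terms[1]))
    }
    sp <- terms[1]
    if (sp %in% names(entries)) {
      stop_tc("parse_error",
              sprintf("taxonomy line %d: duplicate species '%s'", i, sp))
    }
    entries[[sp]] <- terms
  }
  structure(entries, class = "taxonomy")
}

#' Serialize a taxonomy to its line format
#'
#' @param taxonomy a `taxonomy`.
#' @param file optional path to write to.
#' @return character vector of lines (invisibly when `file` is given).
#' @export
serialize_taxonomy <- function(taxonomy, file = NULL) {
  lines <- vapply(taxonomy, paste, character(1), collapse = ";")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  unname(lines)
}

#' Look up the lineage of a species
#'
#' @param taxonomy a `taxonomy`.
#' @param species species name.
#' @return character vector of lineage terms, most specific first.
#' @export
lineage <- function(taxonomy, species) {
  lin <- taxonomy[[species]]
  if (is.null(lin)) {
    stop_tc("unknown_species",
            sprintf("species '%s' is missing from the taxonomy", species))
  }
  lin
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("Taxonomy of %d species\n", length(x)))
  for (sp in utils::head(names(x), 5)) {
    cat(" ", paste(x[[sp]], collapse = ";"), "\n")
  }
  if (length(x) > 5) cat(sprintf("  ... and %d more\n", length(x) - 5))
  invisible(x)
}

split_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\r?\n")[[1]]
  } else {
    as.character(text)
  }
}

# -- sequence mapping ------------------------------------------------------

#' Parse a sequence-to-species mapping
#'
#' A tab-delimited file with exactly two columns: sequence name, species
#' name. The order of rows is preserved.
#'
#' @param text character: file content.
#' @return a data.frame with columns `sequence` and `species`.
#' @export
parse_sequence_mapping <- function(text) {
  lines <- split_lines(text)
  seqs <- character(0)
  spp <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L || !nzchar(trimws(fields[1])) ||
        !nzchar(trimws(fields[2]))) {
      stop_tc("parse_error",
              sprintf("sequence mapping line %d: expected exactly 2 tab-separated columns", i))
    }
    sq <- trimws(fields[1])
    if (sq %in% seqs) {
      stop_tc("parse_error",
              sprintf("sequence mapping line %d: duplicate sequence '%s'", i, sq))
    }
    seqs <- c(seqs, sq)
    spp <- c(spp, trimws(fields[2]))
  }
  data.frame(sequence = seqs, species = spp, stringsAsFactors = FALSE)
}

#' Serialize a sequence-to-species mapping to 2-column TSV lines
#'
#' @param mapping data.frame with columns `sequence`, `species`.
#' @param file optional path to write to.
#' @return character vector of TSV lines (invisibly when `file` is given).
#' @export
serialize_sequence_mapping <- function(mapping, file = NULL) {
  lines <- paste(mapping$sequence, mapping$species, sep = "\t")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

mapping_lookup <- function(mapping, seq_name) {
  i <- match(seq_name, mapping$sequence)
  if (is.na(i)) return(NULL)
  mapping$species[i]
}

# -- species inference -----------------------------------------------------

#' Infer the species from a sequence name
#'
#' Sequence names are assumed to start with the species name in
#' `Genus_species` form (e.g.
#' `Drosophila_melanogaster_fruit_fly_Drosophilidae_AAN09306.2`). When a
#' taxonomy is supplied, the longest underscore-token prefix of the name
#' that matches a known species wins, which resolves species whose names
#' themselves contain more than two tokens (subspecies). Without a
#' taxonomy (or when no prefix matches one of its species) the first two
#' underscore-separated tokens are joined.
#'
#' @param seq_name sequence name.
#' @param taxonomy optional `taxonomy` used for longest-prefix matching.
#' @return the species name.
#' @export
infer_species <- function(seq_name, taxonomy = NULL) {
  stopifnot(is.character(seq_name), length(seq_name) == 1L, nzchar(seq_name))
  tokens <- strsplit(seq_name, "_", fixed = TRUE)[[1]]
  if (!is.null(taxonomy)) {
    for (k in rev(seq_along(tokens))) {
      cand <- paste(tokens[1:k], collapse = "_")
      if (cand %in% names(taxonomy)) return(cand)
    }
  }
  if (length(tokens) < 2L) {
    stop_tc("species_undeterminable",
            sprintf("species undeterminable from sequence name '%s' (fewer than two underscore-separated tokens)",
                    seq_name))
  }
  paste(tokens[1:2], collapse = "_")
}

# -- stop terms ------------------------------------------------------------

#' Parse a stop-terms file
#'
#' One taxonomy term per line; blank lines are ignored and duplicates
#' deduplicated (first occurrence kept).
#'
#' @param text character: file content.
#' @return character vector of stop terms.
#' @export
parse_stop_terms <- function(text) {
  terms <- trimws(split_lines(text))
  unique(terms[nzchar(terms)])
}

#' Bundled default stop terms (family names)
#'
#' Returns the packaged list of taxonomic family names used as stop terms
#' when the user supplies none, so that trees are collapsed at the family
#' level by default. The bundle is a plain-text snapshot (one family per
#' line) shipped under `extdata/family_stop_terms.txt`; it is a curated
#' subset centred on insect and vertebrate families, not the complete
#' official family list.
#'
#' @return character vector of family names.
#' @export
default_stop_terms <- function() {
  path <- system.file("extdata", "family_stop_terms.txt",
                      package = "treecollapse")
  if (!nzchar(path) || !file.exists(path)) {
    stop_tc("configuration",
            "bundled default stop-term list (extdata/family_stop_terms.txt) is missing")
  }
  terms <- parse_stop_terms(readLines(path, warn = FALSE))
  if (length(terms) == 0L) {
    stop_tc("configuration", "bundled default stop-term list is empty")
  }
  terms
}

# -- flattening ------------------------------------------------------------

#' Flatten a taxonomy with stop terms
#'
#' Reduces every lineage to exactly two elements: the species and the
#' first stop term encountered scanning its terms from most specific to
#' most general. After flattening, collapsed groups are named by the stop
#' term itself (e.g. the family name) instead of the lowest common
#' ancestor below it.
#'
#' Lineages containing no stop term are passed through unchanged and a
#' warning (condition class `tc_warning`) is raised naming the species;
#' such species are never collapsed.
#'
#' @param taxonomy a `taxonomy`.
#' @param stops character vector of stop terms.
#' @return the flattened `taxonomy`.
#' @examples
#' tax <- parse_taxonomy(
#'   "Bactrocera_latifrons;Tephritidae;Acalyptratae;Schizophora;Brachycera;Diptera;Eukaryota")
#' serialize_taxonomy(flatten_taxonomy(tax, c("Drosophilidae", "Tephritidae")))
#' @export
flatten_taxonomy <- function(taxonomy, stops) {
  out <- list()
  unmatched <- character(0)
  for (sp in names(taxonomy)) {
    terms <- taxonomy[[sp]]
    hit <- which(terms %in% stops)
    if (length(hit) == 0L) {
      unmatched <- c(unmatched, sp)
      out[[sp]] <- terms
    } else if (hit[1] == 1L) {
      # the species itself is a stop term: nothing below it can collapse,
      # keep the lineage as-is rather than emit a degenerate pair
      out[[sp]] <- terms
    } else {
      out[[sp]] <- c(sp, terms[hit[1]])
    }
  }
  if (length(unmatched) > 0L) {
    warn_tc(sprintf("no stop term found in the lineage of: %s; these species will never be collapsed",
                    paste(unmatched, collapse = ", ")))
  }
  structure(out, class = "taxonomy")
}

warn_tc <- function(message) {
  warning(structure(
    class = c("tc_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

# -- lineage providers and auto-resolution ---------------------------------

#' Offline lineage provider backed by a fixed taxonomy
#'
#' A lineage provider is a function taking a species name and returning
#' its lineage (character vector, most specific first) or `NULL` when the
#' species is unknown. This provider looks species up in a taxonomy held
#' in memory and never touches the network, which keeps pipelines and
#' tests deterministic.
#'
#' @param taxonomy a `taxonomy` acting as the snapshot.
#' @return a provider function.
#' @export
fixture_lineage_provider <- function(taxonomy) {
  force(taxonomy)
  function(species) {
    lin <- taxonomy[[species]]
    if (is.null(lin)) NULL else lin
  }
}

#' NCBI Entrez lineage provider
#'
#' A lineage provider that queries the NCBI Taxonomy database through the
#' Entrez E-utilities (esearch + efetch), with in-memory caching and
#' exponential backoff between retries. Requires network access and the
#' `xml2` package; intended for the opt-in `--fetch-taxonomy` path of the
#' command-line interface. The returned lineage is ordered most specific
#' first (the species itself, then its ranks up to the domain).
#'
#' @param max_tries retry attempts per request.
#' @param delay initial delay in seconds; doubled after every failure.
#' @return a provider function (species name -> lineage or `NULL`).
#' @export
ncbi_lineage_provider <- function(max_tries = 3L, delay = 1) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop_tc("configuration",
            "the NCBI lineage provider requires the 'xml2' package")
  }
  cache <- new.env(parent = emptyenv())
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  fetch <- function(url) {
    wait <- delay
    for (i in seq_len(max_tries)) {
      doc <- tryCatch(xml2::read_xml(url), error = function(e) NULL)
      if (!is.null(doc)) return(doc)
      Sys.sleep(wait)
      wait <- wait * 2
    }
    NULL
  }
  function(species) {
    if (!is.null(cache[[species]])) return(cache[[species]])
    q <- utils::URLencode(gsub("_", " ", species), reserved = TRUE)
    doc <- fetch(sprintf("%s/esearch.fcgi?db=taxonomy&term=%s", base, q))
    if (is.null(doc)) return(NULL)
    id <- xml2::xml_text(xml2::xml_find_first(doc, "//IdList/Id"))
    if (is.na(id) || !nzchar(id)) return(NULL)
    doc <- fetch(sprintf("%s/efetch.fcgi?db=taxonomy&id=%s", base, id))
    if (is.null(doc)) return(NULL)
    taxa <- xml2::xml_find_all(doc, "//LineageEx/Taxon/ScientificName")
    anc <- rev(gsub(" ", "_", xml2::xml_text(taxa)))
    lin <- unique(c(species, anc))
    cache[[species]] <- lin
    lin
  }
}

#' Resolve missing species mappings and lineages
#'
#' Ensures that every tree leaf has a species and every species a lineage.
#' Leaves absent from the supplied mapping get their species inferred from
#' the sequence name (see [infer_species()]); species absent from the
#' supplied taxonomy are looked up through the lineage provider. When both
#' inputs already cover everything they are returned unchanged and the
#' provider is never called.
#'
#' @param leaves character vector of sequence names (the tree leaves).
#' @param mapping optional data.frame (`sequence`, `species`).
#' @param taxonomy optional `taxonomy`.
#' @param provider a lineage provider function (see
#'   [fixture_lineage_provider()]); required only if lineages are missing.
#' @param side_file_prefix optional path prefix (typically the input tree
#'   file). When given and resolution work was done, the completed inputs
#'   are persisted as `<prefix>.sequence_to_species_mapping` and
#'   `<prefix>.taxonomy` so they can be reused.
#' @return list with elements `mapping` and `taxonomy`, both complete.
#' @export
resolve_missing <- function(leaves, mapping = NULL, taxonomy = NULL,
                            provider = NULL, side_file_prefix = NULL) {
  if (is.null(mapping)) {
    mapping <- data.frame(sequence = character(0), species = character(0),
                          stringsAsFactors = FALSE)
  }
  if (is.null(taxonomy)) taxonomy <- structure(list(), class = "taxonomy")

  did_map <- FALSE
  unresolved <- character(0)
  for (leaf in leaves) {
    if (!is.null(mapping_lookup(mapping, leaf))) next
    sp <- tryCatch(infer_species(leaf, taxonomy), tc_error = function(e) NULL)
    if (is.null(sp)) {
      unresolved <- c(unresolved, leaf)
    } else {
      mapping <- rbind(mapping,
                       data.frame(sequence = leaf, species = sp,
                                  stringsAsFactors = FALSE))
      did_map <- TRUE
    }
  }
  if (length(unresolved) > 0L) {
    stop_tc("species_undeterminable",
            sprintf("species undeterminable for tree leaves: %s",
                    paste(unresolved, collapse = ", ")))
  }

  did_tax <- FALSE
  unknown <- character(0)
  need <- setdiff(unique(mapping$species[mapping$sequence %in% leaves]),
                  names(taxonomy))
  if (length(need) > 0L && is.null(provider)) {
    stop_tc("unknown_species",
            sprintf("no lineage available for: %s (supply a taxonomy file or a lineage provider)",
                    paste(need, collapse = ", ")))
  }
  for (sp in need) {
    lin <- provider(sp)
    if (is.null(lin)) {
      unknown <- c(unknown, sp)
    } else {
      taxonomy[[sp]] <- lin
      did_tax <- TRUE
    }
  }
  if (length(unknown) > 0L) {
    stop_tc("unknown_species",
            sprintf("the lineage provider could not resolve: %s",
                    paste(unknown, collapse = ", ")))
  }

  if (!is.null(side_file_prefix) && (did_map || did_tax)) {
    serialize_sequence_mapping(
      mapping, file = paste0(side_file_prefix, ".sequence_to_species_mapping"))
    serialize_taxonomy(taxonomy, file = paste0(side_file_prefix, ".taxonomy"))
  }
  list(mapping = mapping, taxonomy = taxonomy)
}
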