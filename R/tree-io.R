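# Tree input/output: Newick and NEXUS readers, Newick writer.
#
# The parser is a recursive-descent Newick reader that keeps single-leaf
# trees, internal-node labels and full-precision branch lengths, and
# reports malformed input with line:column positions. Square-bracket
# comments (including NEXUS rooting markers [&R]/[&U]) are skipped.

TREE_FORMATS <- c("newick", "nexus", "nexml", "phyloxml", "cdao")

#' Parse a phylogenetic tree
#'
#' Reads a tree from text in one of the supported formats and returns the
#' canonical rooted-tree object used throughout the package. Newick and
#' NEXUS (TREES block, with optional TRANSLATE table) are fully supported;
#' NeXML, PhyloXML and CDAO are admitted in the format enumeration but
#' currently raise an "unsupported dialect" error.
#'
#' Duplicate leaf labels are a hard error: the collapser keys groups by
#' sequence name, so duplicates would silently corrupt group membership.
#'
#' @param text character: the tree text (a single string, possibly
#'   multi-line, or a vector of lines).
#' @param format one of `"newick"`, `"nexus"`, `"nexml"`, `"phyloxml"`,
#'   `"cdao"`.
#' @return a `collapser_tree`.
#' @examples
#' tr <- parse_tree("(A:0.1,B:0.2);")
#' count_leaves(tr)
#' @seealso [write_tree()], [read_tree()], [convert_to_newick()]
#' @export
parse_tree <- function(text, format = "newick") {
  format <- match.arg(tolower(format), TREE_FORMATS)
  text <- paste(text, collapse = "\n")
  switch(format,
    newick = parse_newick(text),
    nexus = parse_nexus(text),
    stop_tc("unsupported_format",
            sprintf("unsupported dialect '%s': only newick and nexus trees can be read",
                    format))
  )
}

#' Read a tree from a file
#'
#' @param path path to the tree file.
#' @inheritParams parse_tree
#' @return a `collapser_tree`.
#' @export
read_tree <- function(path, format = "newick") {
  if (!file.exists(path)) {
    stop_tc("missing_file", sprintf("tree file not found: %s", path))
  }
  parse_tree(readLines(path, warn = FALSE), format = format)
}

# -- Newick ----------------------------------------------------------------

parse_newick <- function(text) {
  st <- new.env(parent = emptyenv())
  st$text <- text
  st$pos <- 1L
  st$n <- nchar(text)

  skip_ws(st)
  root <- nwk_subtree(st)
  skip_ws(st)
  if (peek(st) != ";") nwk_fail(st, "expected ';' at end of tree")
  st$pos <- st$pos + 1L
  skip_ws(st)
  if (st$pos <= st$n) nwk_fail(st, "unexpected trailing content after ';'")
  new_tree(root)
}

peek <- function(st) {
  if (st$pos > st$n) return("")
  substr(st$text, st$pos, st$pos)
}

# whitespace and [...] comments carry no tree structure
skip_ws <- function(st) {
  repeat {
    ch <- peek(st)
    if (ch %in% c(" ", "\t", "\n", "\r")) {
      st$pos <- st$pos + 1L
    } else if (ch == "[") {
      depth <- 1L
      st$pos <- st$pos + 1L
      while (depth > 0L) {
        ch <- peek(st)
        if (ch == "") nwk_fail(st, "unterminated '[' comment")
        if (ch == "[") depth <- depth + 1L
        if (ch == "]") depth <- depth - 1L
        st$pos <- st$pos + 1L
      }
    } else {
      break
    }
  }
}

nwk_fail <- function(st, msg) {
  before <- substr(st$text, 1L, max(st$pos - 1L, 0L))
  nl <- gregexpr("\n", before, fixed = TRUE)[[1]]
  n_nl <- if (nl[1] == -1L) 0L else length(nl)
  line <- n_nl + 1L
  last_nl <- if (n_nl == 0L) 0L else nl[n_nl]
  col <- st$pos - last_nl
  stop_tc("parse_error",
          sprintf("newick parse error at line %d, column %d: %s", line, col, msg))
}

nwk_subtree <- function(st) {
  skip_ws(st)
  if (peek(st) == "(") {
    st$pos <- st$pos + 1L
    children <- list(nwk_subtree(st))
    repeat {
      skip_ws(st)
      ch <- peek(st)
      if (ch == ",") {
        st$pos <- st$pos + 1L
        children[[length(children) + 1L]] <- nwk_subtree(st)
      } else if (ch == ")") {
        st$pos <- st$pos + 1L
        break
      } else if (ch == "") {
        nwk_fail(st, "unexpected end of input inside '(...)'")
      } else {
        nwk_fail(st, sprintf("expected ',' or ')', found '%s'", ch))
      }
    }
    node <- new_node(label = nwk_label(st, required = FALSE),
                     children = children)
  } else {
    lab <- nwk_label(st, required = TRUE)
    node <- new_node(label = lab)
  }
  node$edge_length <- nwk_length(st)
  node
}

nwk_label <- function(st, required = FALSE) {
  skip_ws(st)
  ch <- peek(st)
  if (ch == "'") {
    st$pos <- st$pos + 1L
    out <- character(0)
    repeat {
      ch <- peek(st)
      if (ch == "") nwk_fail(st, "unterminated quoted label")
      if (ch == "'") {
        st$pos <- st$pos + 1L
        if (peek(st) == "'") {        # '' escapes a literal quote
          out <- c(out, "'")
          st$pos <- st$pos + 1L
        } else break
      } else {
        out <- c(out, ch)
        st$pos <- st$pos + 1L
      }
    }
    lab <- paste(out, collapse = "")
    if (!nzchar(lab)) nwk_fail(st, "empty quoted label")
    return(lab)
  }
  m <- regmatches(substr(st$text, st$pos, st$n),
                  regexpr("^[^][(),:;'[:space:]]+",
                          substr(st$text, st$pos, st$n)))
  if (length(m) == 0L || !nzchar(m)) {
    if (required) nwk_fail(st, "expected a leaf label")
    return(NULL)
  }
  st$pos <- st$pos + nchar(m)
  m
}

nwk_length <- function(st) {
  skip_ws(st)
  if (peek(st) != ":") return(NA_real_)
  st$pos <- st$pos + 1L
  skip_ws(st)
  rest <- substr(st$text, st$pos, st$n)
  m <- regmatches(rest,
                  regexpr("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?",
                          rest))
  if (length(m) == 0L || !nzchar(m)) nwk_fail(st, "expected branch length after ':'")
  st$pos <- st$pos + nchar(m)
  as.numeric(m)
}

# -- NEXUS -----------------------------------------------------------------

parse_nexus <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!any(grepl("^\\s*#nexus", lines, ignore.case = TRUE))) {
    stop_tc("parse_error", "not a NEXUS file: missing '#NEXUS' header")
  }
  flat <- paste(lines, collapse = "\n")
  block <- regmatches(flat,
                      regexpr("(?is)begin\\s+trees\\s*;.*?\\bend\\s*;", flat,
                              perl = TRUE))
  if (length(block) == 0L) {
    stop_tc("parse_error", "no TREES block found in NEXUS input")
  }
  block <- block[[1]]

  translate <- nexus_translate_table(block)

  m <- regmatches(block,
                  regexpr("(?is)\\btree\\s+[^=;]+=\\s*[^;]*;", block, perl = TRUE))
  if (length(m) == 0L) {
    stop_tc("parse_error", "TREES block contains no 'tree <name> = ...;' statement")
  }
  nwk <- sub("(?is)^\\s*tree\\s+[^=]+=\\s*", "", m[[1]], perl = TRUE)
  tree <- parse_newick(nwk)
  if (length(translate) > 0L) {
    tree <- new_tree(relabel_node(tree$root, translate))
  }
  tree
}

nexus_translate_table <- function(block) {
  m <- regmatches(block,
                  regexpr("(?is)\\btranslate\\b[^;]*;", block, perl = TRUE))
  if (length(m) == 0L) return(character(0))
  body <- sub("(?is)^\\s*translate\\b", "", m[[1]], perl = TRUE)
  body <- sub(";\\s*$", "", body)
  entries <- strsplit(body, ",", fixed = TRUE)[[1]]
  out <- character(0)
  for (e in entries) {
    e <- trimws(gsub("[\r\n]", " ", e))
    if (!nzchar(e)) next
    key <- sub("\\s.*$", "", e)
    val <- trimws(sub("^\\S+\\s+", "", e))
    val <- gsub("^'|'$", "", val)
    out[key] <- val
  }
  out
}

relabel_node <- function(node, translate) {
  if (!is.null(node$label) && node$label %in% names(translate)) {
    node$label <- unname(translate[[node$label]])
  }
  node$children <- lapply(node$children, relabel_node, translate = translate)
  node
}

# -- Writing ---------------------------------------------------------------

#' Write a tree as Newick text
#'
#' @param tree a `collapser_tree`.
#' @param mode `"cladogram"` (all branch lengths omitted) or `"phylogram"`
#'   (every branch length emitted; requires the tree to carry lengths).
#' @param file optional path; when given the Newick string is also written
#'   to that file.
#' @return the Newick string (terminated by `";"`), invisibly when `file`
#'   is given.
#' @details Labels are sanitized on output: characters that are illegal in
#'   unquoted Newick (spaces, parentheses, commas, colons, semicolons,
#'   quotes, brackets) are replaced by underscores, so synthesized
#'   collapsed-group names stay machine-readable.
#' @export
write_tree <- function(tree, mode = c("cladogram", "phylogram"), file = NULL) {
  stopifnot(inherits(tree, "collapser_tree"))
  mode <- match.arg(mode)
  if (mode == "phylogram" && !tree$has_lengths) {
    stop_tc("lengths_required",
            "phylogram output requested but the input phylogenetic tree must include branch lengths")
  }
  out <- paste0(nwk_emit(tree$root, with_lengths = mode == "phylogram"), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

nwk_emit <- function(node, with_lengths) {
  lab <- if (is.null(node$label)) "" else sanitize_label(node$label)
  core <- if (is_leaf_node(node)) {
    lab
  } else {
    paste0("(",
           paste(vapply(node$children, nwk_emit, character(1),
                        with_lengths = with_lengths),
                 collapse = ","),
           ")", lab)
  }
  if (with_lengths && !is.na(node$edge_length)) {
    core <- paste0(core, ":", fmt_len(node$edge_length))
  }
  core
}

fmt_len <- function(x) sprintf("%.12g", x)

sanitize_label <- function(x) gsub("[][(),:;'\"[:space:]]", "_", x)

#' Convert a tree file to Newick, writing a `.nwk` sibling file
#'
#' Reads a tree file in any supported format and writes its Newick
#' translation next to the original as `<input>.nwk` (the convention used
#' for non-Newick inputs so the converted tree can be reused). For Newick
#' input the file content is copied verbatim.
#'
#' @param path input tree file.
#' @param format the input format (see [parse_tree()]).
#' @return the path of the `.nwk` file, invisibly.
#' @export
convert_to_newick <- function(path, format = "newick") {
  format <- match.arg(tolower(format), TREE_FORMATS)
  out <- paste0(path, ".nwk")
  if (format == "newick") {
    if (!file.exists(path)) {
      stop_tc("missing_file", sprintf("tree file not found: %s", path))
    }
    if (!file.copy(path, out, overwrite = TRUE)) {
      stop_tc("io_error", sprintf("cannot write converted tree to %s", out))
    }
    return(invisible(out))
  }
  tree <- read_tree(path, format = format)
  mode <- if (tree$has_lengths) "phylogram" else "cladogram"
  write_tree(tree, mode = mode, file = out)
  invisible(out)
}
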