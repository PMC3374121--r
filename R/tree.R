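# Haplogroup tree model: nodes, defining markers, branch bipartitions.

#' Read a haplogroup tree specification
#'
#' Parses a tab-separated tree specification into a validated `haplo_tree`
#' object. The file has a header line `node<TAB>parent<TAB>markers`; each
#' subsequent line defines one haplogroup node. `parent` is the label of an
#' existing node, or the token `ROOT` for the (single) root. `markers` holds
#' zero or more semicolon-separated marker definitions of the form
#' `NAME:ANC>DER[:rsID[:POS]]`, e.g. `M123:C>T:na:20223974`. A node with no
#' defining marker (empty `markers` field) is a display class (such as the
#' combined leaf groups of a published tree figure): it can be assigned a
#' frequency but is never a cuttable branch, because no mutation defines it.
#'
#' Marker coordinates are stored verbatim as metadata; no reference-genome
#' arithmetic is ever performed on them.
#'
#' @param file Path to the tree specification, or a connection / character
#'   vector of lines (anything `read.delim` accepts via `text` when given a
#'   character vector with embedded newlines is also fine through
#'   [haplo_tree_from_text()]).
#' @return A `haplo_tree` object: a list with elements `nodes` (named list of
#'   node records with `label`, `parent`, `children`, `markers`), `root`
#'   (root label), `marker_index` (named character vector, marker name to
#'   node label) and `markers` (data.frame of marker definitions with columns
#'   `name`, `ancestral`, `derived`, `rs_id`, `position`, `node`).
#' @seealso [imputable_branches()], [redundancy_filter()], [branch_status()],
#'   [yhap_example()] for the packaged tree fixture.
#' @export
read_haplo_tree <- function(file) {
  df <- read.delim(file, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", blank.lines.skip = TRUE,
                   strip.white = TRUE)
  build_haplo_tree(df)
}

#' Build a haplogroup tree from text
#'
#' Convenience wrapper around [read_haplo_tree()] for a tree specification
#' held in a single string (used heavily in tests and examples).
#'
#' @param text Character scalar holding the full TSV tree specification.
#' @return A `haplo_tree`; see [read_haplo_tree()].
#' @export
haplo_tree_from_text <- function(text) {
  df <- read.delim(text = text, header = TRUE, sep = "\t",
                   comment.char = "#", colClasses = "character",
                   blank.lines.skip = TRUE, strip.white = TRUE)
  build_haplo_tree(df)
}

build_haplo_tree <- function(df) {
  need <- c("node", "parent", "markers")
  if (!all(need %in% names(df)))
    stop("tree spec must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("tree spec has no node records")
  labels <- df$node
  if (anyDuplicated(labels))
    stop("duplicate node label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (any(labels == "" | is.na(labels)))
    stop("empty node label at line ", which(labels == "" | is.na(labels))[1] + 1L)

  roots <- labels[df$parent == "ROOT"]
  if (length(roots) == 0L) stop("no root node (parent token ROOT) found")
  if (length(roots) > 1L)
    stop("multiple roots: ", paste(roots, collapse = ", "))
  dangling <- setdiff(df$parent, c(labels, "ROOT"))
  if (length(dangling))
    stop("parent label(s) not defined as nodes: ",
         paste(dangling, collapse = ", "))

  mk_list <- lapply(seq_len(nrow(df)), function(i) {
    parse_marker_field(df$markers[i], df$node[i], line = i + 1L)
  })
  markers <- do.call(rbind, mk_list)
  if (is.null(markers))
    markers <- data.frame(name = character(), ancestral = character(),
                          derived = character(), rs_id = character(),
                          position = character(), node = character(),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(markers$name))
    stop("marker(s) attached to more than one node or repeated: ",
         paste(unique(markers$name[duplicated(markers$name)]), collapse = ", "))

  nodes <- setNames(vector("list", length(labels)), labels)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    nodes[[lab]] <- list(
      label   = lab,
      parent  = if (df$parent[i] == "ROOT") NA_character_ else df$parent[i],
      children = character(),
      markers = markers$name[markers$node == lab]
    )
  }
  for (lab in labels) {
    p <- nodes[[lab]]$parent
    if (!is.na(p)) nodes[[p]]$children <- c(nodes[[p]]$children, lab)
  }

  tree <- structure(list(
    nodes = nodes, root = roots,
    marker_index = setNames(markers$node, markers$name),
    markers = markers), class = "haplo_tree")

  # reachability doubles as the cycle check: parents all exist and are
  # unique, so any unreachable node would sit on a cycle detached from root
  seen <- tree_preorder(tree)
  if (length(seen) != length(labels))
    stop("cycle or unreachable node(s): ",
         paste(setdiff(labels, seen), collapse = ", "))
  tree
}

parse_marker_field <- function(field, node, line) {
  if (is.na(field) || field == "") return(NULL)
  toks <- strsplit(field, ";", fixed = TRUE)[[1]]
  out <- lapply(toks, function(tok) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("malformed marker definition '", tok, "' at line ", line)
    al <- strsplit(parts[2], ">", fixed = TRUE)[[1]]
    if (length(al) != 2L || any(al == ""))
      stop("malformed allele pair '", parts[2], "' at line ", line)
    if (al[1] == al[2])
      stop("ancestral and derived alleles identical for marker '",
           parts[1], "' at line ", line)
    data.frame(name = parts[1], ancestral = al[1], derived = al[2],
               rs_id = if (length(parts) >= 3L) parts[3] else NA_character_,
               position = if (length(parts) >= 4L) parts[4] else NA_character_,
               node = node, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("haplo_tree:", length(x$nodes), "nodes,",
      nrow(x$markers), "markers, root =", x$root, "\n")
  leaves <- names(x$nodes)[vapply(x$nodes, function(n)
    length(n$children) == 0L, logical(1))]
  cat("  leaves (", length(leaves), "): ",
      paste(utils::head(leaves, 8), collapse = ", "),
      if (length(leaves) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# -- traversal helpers --------------------------------------------------------

tree_preorder <- function(tree) {
  out <- character(0)
  stack <- tree$root
  while (length(stack)) {
    lab <- stack[1]; stack <- stack[-1]
    out <- c(out, lab)
    stack <- c(tree$nodes[[lab]]$children, stack)
  }
  out
}

tree_ancestors <- function(tree, label) {
  out <- character(0)
  p <- tree$nodes[[label]]$parent
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$nodes[[p]]$parent
  }
  out
}

#' Root-to-node path of a haplogroup
#'
#' @param tree A `haplo_tree`.
#' @param label Node label.
#' @return Character vector of node labels from the root down to `label`,
#'   inclusive. A man assigned to haplogroup `label` carries the derived
#'   allele at every marker attached to these nodes and the ancestral allele
#'   everywhere else.
#' @export
tree_path <- function(tree, label) {
  if (is.null(tree$nodes[[label]])) stop("unknown node: ", label)
  rev(c(label, tree_ancestors(tree, label)))
}

tree_siblings <- function(tree, label) {
  p <- tree$nodes[[label]]$parent
  if (is.na(p)) return(character(0))
  setdiff(tree$nodes[[p]]$children, label)
}

# nodes defined by at least one marker, i.e. true cuttable branches
branch_nodes <- function(tree) {
  names(tree$nodes)[vapply(tree$nodes, function(n)
    length(n$markers) > 0L, logical(1))]
}

#' Nodes typed by a set of genotyped markers
#'
#' @param tree A `haplo_tree`.
#' @param genotyped_markers Character vector of marker names that were
#'   genotyped (and survived sample-level QC).
#' @return Character vector of node labels with at least one genotyped
#'   defining marker.
#' @export
typed_nodes <- function(tree, genotyped_markers) {
  unknown <- setdiff(genotyped_markers, tree$markers$name)
  if (length(unknown))
    stop("marker(s) not in tree: ", paste(unknown, collapse = ", "))
  unique(unname(tree$marker_index[genotyped_markers]))
}

#' Untyped branches that can be imputed from the tree
#'
#' A branch carries a defining mutation; a man's carrier status at an
#' untyped branch `B` is derivable when his status at `B`'s parent and at
#' every sibling of `B` is known: he carries `B` exactly when he carries the
#' parent mutation but none of the sibling mutations. (When `B`'s parent is
#' the root, every man "carries" the parent.) By default the rule is applied
#' to a fixpoint, so that branches imputed in one pass count as known in the
#' next — a chain of nested untyped branches flanked by typed sisters (for
#' example a superclade and its internal subclade) all become imputable.
#' Only marker-bearing nodes are candidates: a display class without a
#' defining mutation is not a cuttable branch.
#'
#' @param tree A `haplo_tree`.
#' @param typed_set Character vector of node labels whose defining markers
#'   were genotyped (see [typed_nodes()]). Must be a subset of tree nodes.
#' @param recursive When `TRUE` (default), iterate until no new branch
#'   becomes imputable; when `FALSE`, apply the parent-and-all-siblings rule
#'   once against `typed_set` only.
#' @return A data.frame with one row per imputable branch: `branch`,
#'   `parent` (label, `NA` for a root child), `siblings`
#'   (semicolon-collapsed, alphabetical) and `round` (closure pass on which
#'   it became imputable; all 1 when `recursive = FALSE`). Rows are ordered
#'   by round then branch label, so the result is invariant to the child
#'   ordering of the input tree. Zero rows when nothing is imputable.
#' @export
imputable_branches <- function(tree, typed_set, recursive = TRUE) {
  stray <- setdiff(typed_set, names(tree$nodes))
  if (length(stray))
    stop("typed_set label(s) not in tree: ", paste(stray, collapse = ", "))
  candidates <- setdiff(branch_nodes(tree), c(typed_set, tree$root))
  known <- typed_set
  rows <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    found <- character(0)
    for (b in sort(candidates)) {
      p <- tree$nodes[[b]]$parent
      sibs <- tree_siblings(tree, b)
      ok_parent <- is.na(p) || p == tree$root || p %in% known
      if (ok_parent && all(sibs %in% known)) {
        found <- c(found, b)
        rows[[b]] <- data.frame(
          branch = b,
          parent = if (is.na(p)) NA_character_ else p,
          siblings = paste(sort(sibs), collapse = ";"),
          round = round, stringsAsFactors = FALSE)
      }
    }
    if (length(found) == 0L || !recursive) break
    known <- c(known, found)
    candidates <- setdiff(candidates, found)
  }
  if (length(rows) == 0L)
    return(data.frame(branch = character(), parent = character(),
                      siblings = character(), round = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$round, out$branch), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop imputed branches redundant with a directly genotyped neighbour
#'
#' An imputed branch whose derived-allele frequency is essentially identical
#' to that of a directly genotyped parent or child branch defines (up to a
#' negligible set of men) the same bipartition, so testing it adds nothing.
#' Such branches are removed from the analysis set when their frequency
#' differs from a directly genotyped direct parent or child by less than
#' `threshold`. Directly genotyped branches are never dropped in favour of
#' imputed ones (nor in favour of each other: nested genotyped branches with
#' near-identical frequencies are all reported). Only direct parent/child
#' pairs are compared, not arbitrary ancestors.
#'
#' @param tree A `haplo_tree`.
#' @param branch_freqs Named numeric vector of derived-allele frequencies
#'   (typically in pooled controls) covering every branch under
#'   consideration, genotyped neighbours included. All values in \[0, 1\].
#' @param typed_set Character vector of directly genotyped branch labels.
#' @param threshold Frequency difference below which an imputed branch is
#'   redundant. Default 0.001; with 0, nothing is ever removed.
#' @return Character vector: the retained branch labels, in input order.
#' @export
redundancy_filter <- function(tree, branch_freqs, typed_set,
                              threshold = 0.001) {
  if (is.null(names(branch_freqs)) || any(names(branch_freqs) == ""))
    stop("branch_freqs must be a fully named vector")
  if (any(is.na(branch_freqs)))
    stop("missing frequency for branch(es): ",
         paste(names(branch_freqs)[is.na(branch_freqs)], collapse = ", "))
  if (any(branch_freqs < 0 | branch_freqs > 1))
    stop("frequencies must lie in [0, 1]")
  stray <- setdiff(names(branch_freqs), names(tree$nodes))
  if (length(stray))
    stop("branch(es) not in tree: ", paste(stray, collapse = ", "))

  keep <- vapply(names(branch_freqs), function(b) {
    if (b %in% typed_set) return(TRUE)
    nb <- c(tree$nodes[[b]]$parent, tree$nodes[[b]]$children)
    nb <- intersect(nb[!is.na(nb)], typed_set)
    nb <- intersect(nb, names(branch_freqs))
    if (length(nb) == 0L) return(TRUE)
    all(abs(branch_freqs[b] - branch_freqs[nb]) >= threshold)
  }, logical(1))
  names(branch_freqs)[keep]
}

#' Path to a packaged example file
#'
#' The package ships two plain-text fixtures under `extdata`:
#' \describe{
#'   \item{`y_tree.tsv`}{A Y haplogroup tree covering the 34-marker
#'     genotyping panel of a large European-ancestry prostate cancer study
#'     plus the four untyped branches reachable by imputation (DE via M203,
#'     IJK via M522, IJ via M429, J1 via M267) and three combined display
#'     leaves. Alleles, rs numbers and build-36 positions for the 26
#'     polymorphic panel markers are as published; annotations for the eight
#'     backbone markers that are monomorphic in European-ancestry samples
#'     (M91, M60, M130, M174, M2, M69, M20, M175) are synthetic
#'     placeholders.}
#'   \item{`study_effects_e1b1b1c.tsv`}{Published per-study allelic odds
#'     ratios with 95% confidence intervals for the E1b1b1c (M123) and
#'     R1b1a2 (M269) haplogroups, by case subgroup, feeding the
#'     fixed-effect meta-analysis.}
#' }
#'
#' @param file File name within `extdata`; with no argument, lists the
#'   available files.
#' @return Full path to the file (or a character vector of file names).
#' @export
yhap_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "yhapassoc")))
  path <- system.file("extdata", file, package = "yhapassoc")
  if (path == "") stop("no packaged file named '", file, "'")
  path
}
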