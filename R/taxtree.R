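#' Build a taxonomy tree from core-test results
#'
#' Arranges lineages as a rank-nested tree (a trie over the taxonomy
#' strings): lineages sharing a prefix share the corresponding internal
#' nodes, and each distinct lineage ends in a leaf annotated with its
#' q-value and a group-of-origin tag. This is a taxonomy tree, not an
#' inferred phylogeny — relationships reflect the classification labels
#' only. Empty ranks (`"f__"`) terminate a lineage's path, so no chains
#' of unnamed nodes are created.
#'
#' @param results a `coremic_results` data.frame (typically subset to
#'   `is_core` rows), or a character vector of lineages. An optional
#'   `group` column tags each leaf (default `"interest"`).
#' @return an object of class `taxonomy_tree`.
#' @export
build_tree <- function(results) {
  if (is.character(results))
    results <- data.frame(taxonomy = results, q_value = NA_real_,
                          stringsAsFactors = FALSE)
  lineages <- canonicalize_lineage(results$taxonomy)
  qs <- if ("q_value" %in% names(results)) results$q_value else
    rep(NA_real_, length(lineages))
  tags <- if ("group" %in% names(results)) results$group else
    rep("interest", length(lineages))
  # keep first occurrence of each distinct lineage
  keep <- !duplicated(lineages)
  lineages <- lineages[keep]; qs <- qs[keep]; tags <- tags[keep]
  root <- new_tnode("root")
  # insert in sorted order so the built tree is independent of input order
  o <- order(lineages)
  for (i in o) {
    lp <- lineage_parts(lineages[i])
    named <- nzchar(lp$name)
    stop_at <- if (any(!named)) which(!named)[1] - 1L else length(lp$part)
    path <- lp$part[seq_len(stop_at)]
    if (length(path) == 0L) next  # fully unnamed lineage: nothing to place
    root <- insert_path(root, path, q = qs[i], tag = tags[i],
                        lineage = lineages[i])
  }
  structure(list(root = root), class = "taxonomy_tree")
}

new_tnode <- function(label) {
  list(label = label, children = list(), q = NA_real_,
       tag = NA_character_, lineage = NA_character_)
}

insert_path <- function(node, path, q, tag, lineage) {
  if (length(path) == 0L) {
    node$q <- q
    node$tag <- tag
    node$lineage <- lineage
    return(node)
  }
  key <- path[1]
  if (is.null(node$children[[key]]))
    node$children[[key]] <- new_tnode(key)
  node$children[[key]] <- insert_path(node$children[[key]], path[-1],
                                      q, tag, lineage)
  node
}

tree_leaves <- function(node) {
  if (length(node$children) == 0L) return(list(node))
  unlist(lapply(node$children, tree_leaves), recursive = FALSE)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  n <- length(tree_leaves(x$root))
  cat(sprintf("taxonomy_tree: %d leaf taxa\n",
              if (length(x$root$children) == 0L) 0L else n))
  invisible(x)
}

# quote a Newick label if it contains reserved characters
newick_label <- function(label) {
  if (grepl("[][();:, '\t]", label))
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  else label
}

newick_node <- function(node, with_comments) {
  lab <- newick_label(node$label)
  if (length(node$children) > 0L) {
    inner <- vapply(node$children, newick_node, character(1),
                    with_comments = with_comments)
    return(paste0("(", paste(inner, collapse = ","), ")", lab))
  }
  if (with_comments && !is.na(node$lineage)) {
    # comment content must not contain Newick-structural characters;
    # rank separators become "|"
    clean <- gsub(";", "|", node$lineage, fixed = TRUE)
    clean <- gsub("[][(),']", "", clean)
    lab <- paste0(lab, "[", clean, "]")
  }
  lab
}

#' Export a taxonomy tree as Newick
#'
#' Internal node labels are the rank names; each leaf carries the
#' terminal rank name plus (optionally) the sanitized full lineage in a
#' bracketed comment. Labels containing Newick-reserved characters are
#' single-quoted. The output is parseable by standard Newick readers such
#' as `ape::read.tree`.
#'
#' @param tree a `taxonomy_tree`.
#' @param path output file path.
#' @param with_comments append the full lineage as a `[...]` comment to
#'   each leaf label (default TRUE).
#' @return the Newick string, invisibly; written to `path` if non-NULL.
#' @export
export_newick <- function(tree, path = NULL, with_comments = TRUE) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  nwk <- paste0(newick_node(tree$root, with_comments), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}

render_node <- function(node, depth, annotate) {
  line <- paste0(strrep("  ", depth), node$label)
  if (annotate && length(node$children) == 0L && !is.na(node$q))
    line <- paste0(line, sprintf("  [q=%.3g, %s]", node$q, node$tag))
  c(line, unlist(lapply(node$children, render_node, depth = depth + 1L,
                        annotate = annotate)))
}

#' Render a taxonomy tree as indented text
#'
#' One line per node, two spaces of indentation per rank level. With
#' `annotate = TRUE`, leaves are suffixed with their q-value (3
#' significant digits) and group tag, the text stand-in for the colored
#' significance display of graphical tree viewers.
#'
#' @param tree a `taxonomy_tree`.
#' @param annotate annotate leaves with q-values and group tags?
#' @return character vector of lines.
#' @export
render_ascii <- function(tree, annotate = FALSE) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  unname(render_node(tree$root, 0L, annotate))
}
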