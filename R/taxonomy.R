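# Toy taxonomy support for the phylogenetic feature.
#
# A taxonomy is a rooted tree stored as a named parent-pointer vector.
# The similarity of two taxa is 1/(1 + n) where n is the number of edges on
# the path between their nodes.

#' Build a taxonomy from child-parent edges
#'
#' @param children,parents character vectors of equal length; the root is
#'   the (single) parent that never appears as a child.
#' @return object of class `taxonomy_tree`.
#' @export
taxonomy_from_edges <- function(children, parents) {
  children <- as.character(children)
  parents <- as.character(parents)
  if (length(children) != length(parents)) stopf("children/parents length mismatch")
  if (anyDuplicated(children)) stopf("duplicated child node(s)")
  parent <- setNames(parents, children)
  roots <- setdiff(parents, children)
  if (length(unique(roots)) != 1L)
    stopf("taxonomy must have a single root (found: %s)",
          paste(unique(roots), collapse = ", "))
  # cycle check: every node must reach the root
  for (n in children) {
    seen <- character(0)
    while (n %in% names(parent)) {
      if (n %in% seen) stopf("cycle in taxonomy at node '%s'", n)
      seen <- c(seen, n)
      n <- parent[[n]]
    }
  }
  structure(list(parent = parent, root = unique(roots)), class = "taxonomy_tree")
}

#' Read a taxonomy from a file
#'
#' Tab-separated child-parent rows (`child<TAB>parent`), or a Newick file
#' (`format = "newick"`, requires the ape package): internal node labels are
#' used as parents, unlabeled nodes get synthetic labels.
#'
#' @param path input file.
#' @param format `"tsv"` or `"newick"`.
#' @return a `taxonomy_tree`.
#' @export
read_taxonomy <- function(path, format = c("tsv", "newick")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, header = FALSE, col.names = c("child", "parent"),
                     stringsAsFactors = FALSE)
    return(taxonomy_from_edges(df$child, df$parent))
  }
  if (!requireNamespace("ape", quietly = TRUE))
    stopf("reading Newick taxonomies requires the ape package")
  tr <- ape::read.tree(path)
  nlab <- tr$node.label
  if (is.null(nlab)) nlab <- rep("", tr$Nnode)
  nlab[nlab == ""] <- sprintf("node%d", which(nlab == ""))
  labels <- c(tr$tip.label, nlab)
  taxonomy_from_edges(labels[tr$edge[, 2]], labels[tr$edge[, 1]])
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy: %d nodes, root '%s'\n", length(x$parent) + 1L, x$root))
  invisible(x)
}

taxonomy_depth_path <- function(tree, node) {
  path <- node
  while (node %in% names(tree$parent)) {
    node <- tree$parent[[node]]
    path <- c(path, node)
  }
  path
}

#' Taxonomic similarity of two taxa
#'
#' `1 / (1 + n)` where n is the edge count of the path between the two
#' nodes; same species gives 1, siblings give 1/3.
#'
#' @param taxA,taxB node names.
#' @param tree a `taxonomy_tree`.
#' @return similarity in `(0, 1]`, or `NA` when a taxon is unknown.
#' @export
taxonomy_similarity <- function(taxA, taxB, tree) {
  nodes <- c(names(tree$parent), tree$root)
  if (!(taxA %in% nodes) || !(taxB %in% nodes)) {
    warnf("unknown taxon '%s'; phylogenetic feature flagged missing",
          if (taxA %in% nodes) taxB else taxA)
    return(NA_real_)
  }
  if (taxA == taxB) return(1)
  pa <- taxonomy_depth_path(tree, taxA)
  pb <- taxonomy_depth_path(tree, taxB)
  common <- intersect(pa, pb)
  lca <- common[1L]  # paths are ordered leaf -> root
  n <- (match(lca, pa) - 1L) + (match(lca, pb) - 1L)
  1 / (1 + n)
}
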