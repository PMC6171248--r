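# Newick I/O, Robinson-Foulds congruence, supported-node counting and
# dendrogram-to-tree conversion.

#' Read a Newick tree
#'
#' Numeric internal-node labels are interpreted as integer support values
#' (accessible via [count_supported_nodes()]). The bracketed-comment Newick
#' dialect is not supported and is rejected with a clear message.
#'
#' @param source Path to a Newick file, or a Newick string.
#' @return A `phylo` tree.
#' @export
read_newick <- function(source) {
  text <- if (file.exists(source)) paste(readLines(source, warn = FALSE),
                                         collapse = "") else source
  if (grepl("[", text, fixed = TRUE))
    stop("bracketed Newick comments are not supported; strip '[...]' annotations first",
         call. = FALSE)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("unbalanced parentheses in Newick input (%d '(' vs %d ')')",
                 n_open, n_close), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop(sprintf("Newick parse error: %s",
                                                    conditionMessage(e)),
                                            call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: no tree found", call. = FALSE)
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are preserved to 10 significant digits; internal-node
#' labels (support values) are written as-is.
#'
#' @param tree A `phylo` tree.
#' @param path Output path; if omitted the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  text <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(path)
}

#' Robinson-Foulds symmetric difference between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' trees, both treated as unrooted (set `rooted = TRUE` to compare rooted
#' clades instead). Polytomies simply contribute fewer bipartitions. Two
#' trees with identical splits give 0; the maximum for binary unrooted trees
#' on n leaves is 2(n-3).
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @param rooted Compare rooted clades rather than unrooted splits.
#' @return Integer symmetric difference.
#' @export
robinson_foulds <- function(t1, t2, rooted = FALSE) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    d1 <- setdiff(t1$tip.label, t2$tip.label)
    d2 <- setdiff(t2$tip.label, t1$tip.label)
    stop(sprintf("leaf sets differ; only in tree 1: {%s}; only in tree 2: {%s}",
                 paste(d1, collapse = ", "), paste(d2, collapse = ", ")),
         call. = FALSE)
  }
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE, rooted = rooted))
}

#' Count well-supported internal nodes
#'
#' Internal nodes whose (numeric) label is at least `threshold`. Non-numeric
#' or missing labels are not counted.
#'
#' @param tree A `phylo` tree with support values as internal-node labels.
#' @param threshold Inclusive support threshold, default 80.
#' @return Integer count.
#' @export
count_supported_nodes <- function(tree, threshold = 80) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$node.label
  if (is.null(labs)) return(0L)
  vals <- suppressWarnings(as.numeric(labs))
  sum(!is.na(vals) & vals >= threshold)
}

#' Convert a merge tree (dendrogram) to a phylogenetic tree
#'
#' A merge at height h becomes an internal node at depth h/2 from the leaves,
#' so the result is ultrametric and leaf-to-leaf path lengths equal merge
#' heights. Enables Robinson-Foulds comparison between content dendrograms
#' and phylogenies.
#'
#' @param mt An `hclust` object.
#' @return A rooted binary `phylo` tree.
#' @export
mergetree_to_phylotree <- function(mt) {
  stopifnot(inherits(mt, "hclust"))
  ape::as.phylo(mt)
}
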