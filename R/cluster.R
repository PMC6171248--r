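# Agglomerative hierarchical clustering of genome distance matrices, with the
# quality measures used to choose and evaluate dendrograms: the agglomerative
# coefficient, silhouettes, and the adjusted Rand index between partitions.

LINKAGE_METHODS <- c(ward = "ward.D2", average = "average",
                     complete = "complete", single = "single")

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Lance-Williams agglomeration under the chosen update rule. `"ward"` maps to
#' Ward.D2 (squared-distance update), applied to Jaccard distances even though
#' these are non-Euclidean; the variant is recorded in the result's `$method`.
#'
#' @param dist Symmetric zero-diagonal distance matrix or `dist` object.
#' @param method One of `"ward"`, `"average"`, `"complete"`, `"single"`.
#' @return An `hclust` merge tree (n-1 merges with non-negative heights).
#' @export
hierarchical_cluster <- function(dist, method = c("ward", "average",
                                                  "complete", "single")) {
  method <- match.arg(method)
  d <- assert_distance_matrix(dist, "dist")
  stats::hclust(stats::as.dist(d), method = LINKAGE_METHODS[[method]])
}

#' Agglomerative coefficient of a merge tree
#'
#' One minus the average, over leaves, of the ratio between the height at
#' which the leaf first merges and the height of the final merge. Values near
#' 1 indicate clear cluster structure; near 0, a single undifferentiated
#' cluster. If all points are identical (final height 0) the coefficient is
#' defined as 0, with a warning.
#'
#' @param mt An `hclust` object.
#' @return The agglomerative coefficient, in \[0,1\].
#' @export
agglomerative_coefficient <- function(mt) {
  stopifnot(inherits(mt, "hclust"))
  n <- length(mt$order)
  if (n < 2) stop("need at least 2 leaves", call. = FALSE)
  final <- mt$height[length(mt$height)]
  if (final <= 0) {
    warning("final merge height is 0 (all points identical); coefficient defined as 0",
            call. = FALSE)
    return(0)
  }
  first <- numeric(n)
  for (s in seq_along(mt$height)) {
    leaves <- -mt$merge[s, ][mt$merge[s, ] < 0]
    first[leaves] <- mt$height[s]
  }
  1 - mean(first / final)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges. Cluster labels are assigned in order of
#' leaf appearance: the first leaf (in label order of the input) is in
#' cluster 1, the first leaf in a different cluster starts cluster 2, etc.
#'
#' @param mt An `hclust` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector, leaf -> cluster label in `1..k`.
#' @export
cut_dendrogram <- function(mt, k) {
  stopifnot(inherits(mt, "hclust"))
  n <- length(mt$order)
  assert_count(k, "k", min = 1)
  if (k > n) stop(sprintf("k = %d exceeds the number of leaves (%d)", k, n),
                  call. = FALSE)
  part <- stats::cutree(mt, k = k)
  relabel <- match(part, unique(part))
  names(relabel) <- names(part)
  relabel
}

#' Per-genome silhouette values
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean distance to the
#' other members of i's cluster and `b` the smallest mean distance to another
#' cluster; members of singleton clusters get 0. Values lie in \[-1, 1\];
#' values near 1 mean the unit clearly belongs to its cluster.
#'
#' @param dist Distance matrix or `dist` over the genomes.
#' @param part Named cluster assignment (see [cut_dendrogram()]), k >= 2.
#' @return Named numeric vector of silhouette values.
#' @export
silhouette_values <- function(dist, part) {
  d <- assert_distance_matrix(dist, "dist")
  if (!is.null(names(part))) {
    if (!setequal(names(part), rownames(d)))
      stop("partition names do not match the distance matrix", call. = FALSE)
    part <- part[rownames(d)]
  } else if (length(part) != nrow(d)) {
    stop("partition length does not match the distance matrix", call. = FALSE)
  }
  if (length(unique(part)) < 2)
    stop("silhouettes require at least 2 clusters", call. = FALSE)
  sil <- cluster::silhouette(as.integer(factor(part)), stats::as.dist(d))
  setNames(sil[, "sil_width"], rownames(d))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement from the pair-counting
#' contingency table; 1 for identical partitions (up to label permutation),
#' approximately 0 for independent ones.
#'
#' @param p1,p2 Cluster assignments over the same items; if named, they are
#'   aligned by name.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions cover different item sets", call. = FALSE)
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions have different lengths", call. = FALSE)
  }
  tab <- table(p1, p2)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
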