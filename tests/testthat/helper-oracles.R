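# Independent brute-force oracles used to validate the implementation paths.
# These deliberately share no code with the package internals.

# Non-trivial bipartitions of an unrooted tree, canonicalized as the sorted
# tip set NOT containing the reference (first sorted) leaf, one string each.
oracle_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n <- length(tips)
  desc_tips <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  root <- n + 1L
  internal_children <- tree$edge[tree$edge[, 2] > n, 2]
  splits <- character(0)
  for (node in internal_children) {
    side <- desc_tips(node)
    if (length(side) < 2 || length(side) > n - 2) next
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2) next
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Upper-tail hypergeometric probability by exhaustive pmf summation.
oracle_hyper_tail <- function(k_in, n_sample, K_class, N) {
  js <- k_in:min(n_sample, K_class)
  sum(choose(K_class, js) * choose(N - K_class, n_sample - js)) /
    choose(N, n_sample)
}

# Naive O(n^3) agglomeration re-scanning all inter-cluster distances at each
# step. single/complete/average recompute from the original matrix; ward uses
# the Ward.D2 Lance-Williams update. Returns the merge heights in order.
oracle_agglomerate <- function(d, method) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  cd <- d            # current inter-cluster distances
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  cross_stat <- function(ci, cj)
    switch(method,
           single = min(d[ci, cj]),
           complete = max(d[ci, cj]),
           average = mean(d[ci, cj]))
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      v <- cd[idx[a], idx[b]]
      if (v < best_d - 1e-12) { best_d <- v; best <- c(idx[a], idx[b]) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    merged <- c(clusters[[i]], clusters[[j]])
    for (k in which(active)) {
      if (k == i || k == j) next
      cd[i, k] <- cd[k, i] <- if (method == "ward") {
        ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
        sqrt(((ni + nk) * cd[i, k]^2 + (nj + nk) * cd[j, k]^2 -
                nk * cd[i, j]^2) / (ni + nj + nk))
      } else cross_stat(merged, clusters[[k]])
    }
    clusters[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  heights
}

# Random tree with strictly positive branch lengths and its additive
# (patristic) distance matrix.
random_additive_case <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = stats::cophenetic(tr))
}

random_binary_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  tr
}
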