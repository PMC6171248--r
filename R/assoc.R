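# Cluster-environment association by hypergeometric enrichment across
# dendrogram cuts with FDR control, and detection of putatively adaptive
# (group-specific) gene functions.

#' One-sided hypergeometric over-representation test
#'
#' Tail probability `P(X >= k_in)` of observing at least `k_in` members of a
#' class of size `K_class` in a sample of `n_sample` drawn without replacement
#' from a population of `N`. Computed through the stable log-space tail of
#' [stats::phyper()].
#'
#' @param k_in Observed members of the class in the sample.
#' @param n_sample Sample (cluster) size.
#' @param K_class Class (environment) total in the population.
#' @param N Population size.
#' @return The p-value (vectorized over its arguments).
#' @export
hypergeometric_test <- function(k_in, n_sample, K_class, N) {
  if (any(k_in < 0) || any(n_sample < 0) || any(K_class < 0) || any(N < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(n_sample > N) || any(K_class > N))
    stop("`n_sample` and `K_class` cannot exceed `N`", call. = FALSE)
  if (any(k_in > pmin(n_sample, K_class)))
    stop("`k_in` cannot exceed min(n_sample, K_class)", call. = FALSE)
  exp(stats::phyper(k_in - 1, K_class, N - K_class, n_sample,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1 and
#' returned in the original order.
#'
#' @param pvalues Numeric vector of p-values in \[0,1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Scan dendrogram cuts for cluster-environment associations
#'
#' For each cut size `k` from `k_min` up, the dendrogram is cut and every
#' (cluster, environment) pair is tested for over-representation with the
#' hypergeometric distribution; p-values are BH-adjusted within each cut
#' (set `fdr_scope = "global"` to pool across cuts instead). Cutting continues
#' into smaller groups until a cut yields no significant association, at which
#' point the scan stops; the largest k with any significant row is recorded in
#' the result's `last_significant_k` attribute. Environment classes covering
#' the whole population (or absent) are not tested; the Unknown class is
#' tested like any other but flagged in the output.
#'
#' @param mt An `hclust` dendrogram over the genomes.
#' @param env Named environment vector covering all leaves.
#' @param k_min First cut size (default 3).
#' @param k_max Last cut size to consider (default: number of leaves).
#' @param alpha Significance level on the adjusted q-values (default 0.05).
#' @param fdr_scope `"within_cut"` (default) or `"global"`.
#' @return Data.frame with one row per performed test: k, cluster,
#'   environment, k_in, n_cluster, K_env, N, p, q, significant, unknown_class.
#' @export
scan_cluster_environment_associations <- function(mt, env, k_min = 3,
                                                  k_max = NULL, alpha = 0.05,
                                                  fdr_scope = c("within_cut",
                                                                "global")) {
  stopifnot(inherits(mt, "hclust"))
  fdr_scope <- match.arg(fdr_scope)
  n <- length(mt$order)
  k_max <- k_max %||% n
  assert_count(k_min, "k_min", min = 1)
  assert_count(k_max, "k_max", min = 1)
  if (k_max < k_min) stop("`k_max` must be >= `k_min`", call. = FALSE)
  k_max <- min(k_max, n)
  assert_prob(alpha, "alpha")
  if (is.null(mt$labels)) mt$labels <- as.character(seq_len(n))
  if (!all(mt$labels %in% names(env)))
    stop("environment map does not cover all leaves", call. = FALSE)
  env <- env[mt$labels]

  env_totals <- table(env)
  testable <- names(env_totals)[env_totals > 0 & env_totals < n]

  rows <- list()
  last_significant_k <- NA_integer_
  for (k in k_min:k_max) {
    if (length(testable) == 0) break
    part <- cut_dendrogram(mt, k)
    tab <- table(part, factor(env, levels = testable))
    cluster_sizes <- table(part)
    grid <- expand.grid(cluster = rownames(tab), environment = testable,
                        stringsAsFactors = FALSE)
    grid$k_in <- tab[cbind(grid$cluster, grid$environment)]
    grid$n_cluster <- as.integer(cluster_sizes[grid$cluster])
    grid$K_env <- as.integer(env_totals[grid$environment])
    grid$N <- n
    grid$p <- hypergeometric_test(grid$k_in, grid$n_cluster, grid$K_env, grid$N)
    grid$q <- bh_adjust(grid$p)
    grid <- cbind(k = k, grid)
    any_sig <- any(grid$q <= alpha)
    if (any_sig) last_significant_k <- k
    rows[[length(rows) + 1]] <- grid
    if (!any_sig) break
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(k = integer(0), cluster = character(0), environment = character(0),
               k_in = integer(0), n_cluster = integer(0), K_env = integer(0),
               N = integer(0), p = numeric(0), q = numeric(0))
  if (fdr_scope == "global" && nrow(out) > 0) out$q <- bh_adjust(out$p)
  out$significant <- out$q <= alpha
  out$unknown_class <- out$environment == "Unknown"
  out$cluster <- as.integer(out$cluster)
  rownames(out) <- NULL
  attr(out, "last_significant_k") <- last_significant_k
  out
}

#' Detect putatively adaptive (group-specific) functions
#'
#' For every function and focal group, presence/absence counts in the focal
#' group versus the union of the other groups (or versus each other group with
#' `mode = "pairwise"`) form a 2x2 table tested with a one-sided exact
#' hypergeometric test in the direction of the observed imbalance. After BH
#' adjustment across all (function, group) tests, a function is reported for a
#' group when `q <= alpha` and its presence fraction in the focal group is at
#' least `min_presence` (the >= 80% presence gate). The exact 2x2 presence
#' test is a documented proxy for count-regression approaches to the same
#' question.
#'
#' @param profiles Named list, genome -> set of function IDs.
#' @param groups Named group assignment over the same genomes (>= 2 groups,
#'   none empty).
#' @param min_presence Presence-fraction gate in the focal group, default 0.80.
#' @param alpha FDR significance level, default 0.05.
#' @param mode `"one_vs_rest"` (default) or `"pairwise"` contrasts.
#' @return Data.frame of reported functions: function_id, group (and
#'   `other_group` for pairwise), presence_focal, presence_other, direction
#'   ("over"/"under"), p, q. The full test table (before the q and presence
#'   gates) is attached as attribute `all_tests`.
#' @export
find_adaptive_functions <- function(profiles, groups, min_presence = 0.80,
                                    alpha = 0.05,
                                    mode = c("one_vs_rest", "pairwise")) {
  mode <- match.arg(mode)
  assert_prob(min_presence, "min_presence")
  assert_prob(alpha, "alpha")
  if (!setequal(names(profiles), names(groups)))
    stop("profiles and groups cover different genome sets", call. = FALSE)
  groups <- groups[names(profiles)]
  glev <- sort(unique(as.character(groups)))
  if (length(glev) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(as.character(groups))
  if (any(sizes == 0)) stop("empty group", call. = FALSE)

  fams <- sort(unique(unlist(profiles, use.names = FALSE)))
  if (length(fams) == 0)
    return(data.frame(function_id = character(0), group = character(0),
                      presence_focal = numeric(0), presence_other = numeric(0),
                      direction = character(0), p = numeric(0), q = numeric(0)))
  pres <- vapply(profiles, function(p) fams %in% p, logical(length(fams)))
  counts <- t(rowsum(t(matrix(as.integer(pres), nrow = length(fams),
                              dimnames = list(fams, names(profiles)))),
                     group = as.character(groups)))  # functions x groups

  contrasts <- if (mode == "one_vs_rest") {
    lapply(glev, function(g) list(focal = g, other = setdiff(glev, g),
                                  label = "rest"))
  } else {
    unlist(lapply(glev, function(g)
      lapply(setdiff(glev, g), function(h)
        list(focal = g, other = h, label = h))), recursive = FALSE)
  }

  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    n_f <- sum(sizes[ct$focal])
    n_o <- sum(sizes[ct$other])
    k_f <- counts[, ct$focal, drop = FALSE]
    k_f <- if (length(ct$focal) > 1) rowSums(k_f) else k_f[, 1]
    k_o <- counts[, ct$other, drop = FALSE]
    k_o <- if (length(ct$other) > 1) rowSums(k_o) else k_o[, 1]
    # one-sided tails in both directions; keep the direction actually observed
    p_over <- hypergeometric_test(k_f, n_f, k_f + k_o, n_f + n_o)
    p_under <- exp(stats::phyper(k_f, k_f + k_o, n_o + n_f - k_f - k_o, n_f,
                                 lower.tail = TRUE, log.p = TRUE))
    over <- p_over <= p_under
    data.frame(function_id = rownames(counts),
               group = ct$focal,
               other_group = ct$label,
               presence_focal = k_f / n_f,
               presence_other = k_o / n_o,
               direction = ifelse(over, "over", "under"),
               p = ifelse(over, p_over, p_under),
               stringsAsFactors = FALSE)
  }))
  tests$q <- bh_adjust(tests$p)
  out <- tests[tests$q <= alpha & tests$presence_focal >= min_presence, ,
               drop = FALSE]
  if (mode == "one_vs_rest") out$other_group <- NULL
  out <- out[order(out$q, out$function_id), ]
  rownames(out) <- NULL
  attr(out, "all_tests") <- tests
  out
}
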