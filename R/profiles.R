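# Per-genome functional profiles from domain-assignment tables, and Jaccard
# index / distance matrices over those profiles.

#' Filter domain assignments by PSSM coverage and within-protein overlap
#'
#' Assignments with `pssm_coverage < min_pssm_coverage` are eliminated first.
#' Then, per protein, the surviving assignments are processed best-score-first
#' and an assignment is dropped when its interval overlaps any already retained
#' assignment by more than `max_overlap` (measured, by default, as a fraction
#' of the shorter of the two intervals; 1-based inclusive coordinates).
#' The operation is idempotent: filtering a filtered table changes nothing.
#'
#' @param assignments data.frame with columns `protein_id`, `function_id`,
#'   `score`, `pssm_coverage`, `qstart`, `qend`.
#' @param min_pssm_coverage Minimum PSSM coverage, default 0.70 (assignments
#'   "covering less than 70%" are eliminated).
#' @param max_overlap Maximum allowed overlap fraction, default 0.10.
#' @return The filtered assignments, same columns.
#' @export
filter_assignments <- function(assignments, min_pssm_coverage = 0.70,
                               max_overlap = 0.10) {
  assert_prob(min_pssm_coverage, "min_pssm_coverage")
  assert_prob(max_overlap, "max_overlap")
  need <- c("protein_id", "function_id", "score", "pssm_coverage", "qstart", "qend")
  missing_cols <- setdiff(need, names(assignments))
  if (length(missing_cols) > 0)
    stop(sprintf("assignments lack columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (any(assignments$qstart > assignments$qend))
    stop("assignment interval with start > end", call. = FALSE)
  if (any(assignments$pssm_coverage < 0 | assignments$pssm_coverage > 1))
    stop("pssm_coverage must be in [0, 1]", call. = FALSE)

  a <- assignments[assignments$pssm_coverage >= min_pssm_coverage, , drop = FALSE]
  if (nrow(a) == 0) { rownames(a) <- NULL; return(a) }

  # deterministic processing order: best score first, ties by coverage then ID
  ord <- order(a$protein_id, -a$score, -a$pssm_coverage, a$function_id)
  a <- a[ord, , drop = FALSE]
  keep <- logical(nrow(a))
  for (idx in split(seq_len(nrow(a)), a$protein_id)) {
    retained <- integer(0)
    for (i in idx) {
      s1 <- a$qstart[i]; e1 <- a$qend[i]
      ok <- TRUE
      for (j in retained) {
        ov <- min(e1, a$qend[j]) - max(s1, a$qstart[j]) + 1
        if (ov > 0) {
          shorter <- min(e1 - s1 + 1, a$qend[j] - a$qstart[j] + 1)
          if (ov / shorter > max_overlap) { ok <- FALSE; break }
        }
      }
      if (ok) retained <- c(retained, i)
    }
    keep[retained] <- TRUE
  }
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-genome function profiles
#'
#' @param assignments Filtered assignments (see [filter_assignments()]).
#' @param gene_map Gene map (data.frame or TSV path with `gene_id`,
#'   `genome_id`) resolving each protein to its genome; every genome in the
#'   map receives a profile, empty ones with a warning.
#' @return Named list, genome -> sorted character vector of distinct function IDs.
#' @export
build_profiles <- function(assignments, gene_map) {
  if (is.character(gene_map) && length(gene_map) == 1)
    gene_map <- utils::read.delim(gene_map, stringsAsFactors = FALSE)
  idx <- match(assignments$protein_id, gene_map$gene_id)
  if (anyNA(idx)) {
    missing <- unique(assignments$protein_id[is.na(idx)])
    stop(sprintf("proteins not present in gene map: %s%s",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""), call. = FALSE)
  }
  genomes <- sort(unique(gene_map$genome_id))
  by_genome <- split(assignments$function_id, factor(gene_map$genome_id[idx],
                                                     levels = genomes))
  profiles <- lapply(by_genome, function(f) sort(unique(f)))
  empty <- names(profiles)[lengths(profiles) == 0]
  if (length(empty) > 0)
    warning(sprintf("genomes with empty function profiles: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  profiles
}

#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`. Two empty sets are defined as identical
#' (index 1, distance 0) and flagged with a warning: genomes with no
#' annotations at all are indistinguishable rather than maximally distant.
#'
#' @param a,b Vectors treated as sets.
#' @return The Jaccard index in \[0,1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    warning("Jaccard index of two empty sets defined as 1", call. = FALSE)
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Jaccard distance matrix over function profiles
#'
#' `Jd(A,B) = 1 - J(A,B)` for every genome pair.
#'
#' @param profiles Named list of function sets (see [build_profiles()]).
#' @return Symmetric zero-diagonal distance matrix over the genomes.
#' @export
profile_distance_matrix <- function(profiles) {
  n <- length(profiles)
  if (n < 2) stop("need at least 2 genomes", call. = FALSE)
  genomes <- names(profiles)
  # presence/absence matrix, then vectorized pairwise intersections
  fams <- sort(unique(unlist(profiles, use.names = FALSE)))
  d <- matrix(0, n, n, dimnames = list(genomes, genomes))
  if (length(fams) > 0) {
    m <- vapply(profiles, function(p) fams %in% p, logical(length(fams)))
    m <- matrix(as.numeric(m), nrow = length(fams))
    inter <- crossprod(m)
    sizes <- colSums(m)
    uni <- outer(sizes, sizes, "+") - inter
    j <- ifelse(uni == 0, 1, inter / uni)
    d <- 1 - j
    dimnames(d) <- list(genomes, genomes)
    if (any(uni == 0))
      warning("genome pairs with two empty profiles treated as identical",
              call. = FALSE)
  } else {
    warning("all profiles empty; all distances 0", call. = FALSE)
  }
  diag(d) <- 0
  d
}
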