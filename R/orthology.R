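# Reciprocal-best-hit orthology, core / Core-70 selection, the Genomic
# Similarity Score (GSS), and neighbor-joining on the GSS distance matrix.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore", "qcovs")

# Resolve gene -> genome, either through an explicit map or the "genome|gene"
# ID convention.
resolve_genome <- function(gene_ids, gene_map = NULL) {
  if (!is.null(gene_map)) {
    if (is.character(gene_map) && length(gene_map) == 1)
      gene_map <- utils::read.delim(gene_map, stringsAsFactors = FALSE)
    idx <- match(gene_ids, gene_map$gene_id)
    if (anyNA(idx)) {
      missing <- unique(gene_ids[is.na(idx)])
      stop(sprintf("gene IDs not present in gene map: %s%s",
                   paste(utils::head(missing, 5), collapse = ", "),
                   if (length(missing) > 5) ", ..." else ""), call. = FALSE)
    }
    return(gene_map$genome_id[idx])
  }
  has_pipe <- grepl("|", gene_ids, fixed = TRUE)
  if (!all(has_pipe))
    stop("gene IDs do not follow the 'genome|gene' convention and no gene map was given",
         call. = FALSE)
  sub("\\|.*$", "", gene_ids)
}

#' Read a 13-column BLAST-style hit table
#'
#' Parses the tab-separated BLAST outfmt-6 dialect extended with a 13th
#' `qcovs` column (query coverage as a fraction in \[0,1\]). Gene-to-genome
#' resolution uses a sidecar gene map (`gene_id`, `genome_id` TSV or
#' data.frame) when given, otherwise the `genome|gene` ID convention.
#'
#' @param source Path to the hit-table file (no header line).
#' @param gene_map Optional gene map (path or data.frame).
#' @return A `hit_table` data.frame with the 13 canonical columns plus
#'   resolved `qgenome` and `sgenome`.
#' @export
read_hit_table <- function(source, gene_map = NULL) {
  if (!file.exists(source)) stop(sprintf("no such file: '%s'", source), call. = FALSE)
  empty <- function() {
    out <- as.data.frame(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 11)), HIT_COLUMNS))
    out$qgenome <- character(0); out$sgenome <- character(0)
    class(out) <- c("hit_table", "data.frame")
    out
  }
  if (file.size(source) == 0) return(empty())
  nf <- utils::count.fields(source, sep = "\t", quote = "")
  if (length(nf) == 0) return(empty())
  bad <- which(nf != 13)
  if (length(bad) > 0)
    stop(sprintf(
      "line %d has %d columns; expected 13 (column 13 is qcovs, query coverage)",
      bad[1], nf[bad[1]]), call. = FALSE)
  hits <- data.table::fread(source, sep = "\t", header = FALSE,
                            col.names = HIT_COLUMNS, data.table = FALSE)
  if (any(hits$bitscore < 0))
    stop("negative bitscore encountered; hit table is invalid", call. = FALSE)
  if (any(hits$qcovs < 0 | hits$qcovs > 1))
    stop("qcovs (column 13) must be a fraction in [0, 1]", call. = FALSE)
  hits$qgenome <- resolve_genome(hits$qseqid, gene_map)
  hits$sgenome <- resolve_genome(hits$sseqid, gene_map)
  class(hits) <- c("hit_table", "data.frame")
  hits
}

#' Write a hit table in the 13-column BLAST tabular dialect
#'
#' @param hits A `hit_table` data.frame.
#' @param path Output path; written tab-separated without a header, as BLAST does.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(as.data.frame(hits)[, HIT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Ensure qgenome/sgenome columns exist on a hit table.
with_genomes <- function(hits, gene_map = NULL) {
  if (is.null(hits$qgenome)) hits$qgenome <- resolve_genome(hits$qseqid, gene_map)
  if (is.null(hits$sgenome)) hits$sgenome <- resolve_genome(hits$sseqid, gene_map)
  hits
}

# Core RBH machinery over an arbitrary set of genomes. Ties on bitscore are
# broken by higher percent identity, then longer alignment, then lexicographic
# subject ID, so results are reproducible across runs.
rbh_engine <- function(hits, min_coverage, filter_order = c("before", "after")) {
  filter_order <- match.arg(filter_order)
  dt <- data.table::as.data.table(as.data.frame(hits))

  self <- dt[dt$qseqid == dt$sseqid, ]
  self_scores <- self[, list(self_score = max(bitscore)), by = "qseqid"]

  cross <- dt[dt$qgenome != dt$sgenome, ]
  if (filter_order == "before") cross <- cross[cross$qcovs >= min_coverage, ]
  if (nrow(cross) == 0) return(empty_rbh())
  data.table::setorderv(cross, c("qseqid", "sgenome", "bitscore", "pident",
                                 "length", "sseqid"),
                        order = c(1, 1, -1, -1, -1, 1))
  best <- unique(cross, by = c("qseqid", "sgenome"))
  fwd <- best[, c("qseqid", "sseqid", "qgenome", "sgenome", "bitscore", "qcovs")]
  data.table::setnames(fwd, c("gene_a", "gene_b", "genome_a", "genome_b",
                              "score_ab", "cov_ab"))
  rev <- best[, c("qseqid", "sseqid", "bitscore", "qcovs")]
  data.table::setnames(rev, c("gene_b", "gene_a", "score_ba", "cov_ba"))
  pairs <- as.data.frame(merge(fwd, rev, by = c("gene_a", "gene_b")))
  if (filter_order == "after")
    pairs <- pairs[pairs$cov_ab >= min_coverage & pairs$cov_ba >= min_coverage, ]
  if (nrow(pairs) == 0) return(empty_rbh())

  # canonical orientation: genome_a < genome_b, one row per unordered pair
  flip <- pairs$genome_a > pairs$genome_b
  cols <- c("gene_a", "gene_b", "genome_a", "genome_b",
            "score_ab", "score_ba", "cov_ab", "cov_ba")
  swapped <- c("gene_b", "gene_a", "genome_b", "genome_a",
               "score_ba", "score_ab", "cov_ba", "cov_ab")
  pairs[flip, cols] <- pairs[flip, swapped]
  pairs <- pairs[!duplicated(pairs[c("gene_a", "gene_b")]), ]

  ss <- as.data.frame(self_scores)
  pairs$self_a <- ss$self_score[match(pairs$gene_a, ss$qseqid)]
  pairs$self_b <- ss$self_score[match(pairs$gene_b, ss$qseqid)]
  pairs <- pairs[order(pairs$genome_a, pairs$genome_b, pairs$gene_a), ]
  rownames(pairs) <- NULL
  out <- pairs[, c("genome_a", "genome_b", "gene_a", "gene_b",
                   "score_ab", "score_ba", "self_a", "self_b")]
  class(out) <- c("rbh_set", "data.frame")
  out
}

empty_rbh <- function() {
  out <- data.frame(genome_a = character(0), genome_b = character(0),
                    gene_a = character(0), gene_b = character(0),
                    score_ab = numeric(0), score_ba = numeric(0),
                    self_a = numeric(0), self_b = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("rbh_set", "data.frame")
  out
}

#' Reciprocal best hits between two genomes
#'
#' Hits with query coverage below `min_coverage` are removed first
#' (filter-then-rank; set `filter_order = "after"` to rank first and drop
#' low-coverage pairs afterwards), then a gene pair (a, b) is kept iff b is
#' a's best surviving hit in genome B and a is b's best in genome A.
#'
#' @param hits A `hit_table` (must contain both hit directions and self-hits
#'   if GSS is to be computed downstream).
#' @param genome_a,genome_b Genome identifiers.
#' @param min_coverage Query-coverage threshold, default 0.70 ("at least 70%
#'   of the aligned proteins").
#' @param filter_order Apply the coverage filter `"before"` (default) or
#'   `"after"` best-hit determination.
#' @param gene_map Optional gene map if gene IDs are not `genome|gene`.
#' @return An `rbh_set` data.frame with one row per ortholog pair, both
#'   directed bitscores and both self-scores, oriented so
#'   `genome_a < genome_b`; `find_rbh(A, B)` and `find_rbh(B, A)` are identical.
#' @export
find_rbh <- function(hits, genome_a, genome_b, min_coverage = 0.70,
                     filter_order = c("before", "after"), gene_map = NULL) {
  assert_prob(min_coverage, "min_coverage")
  hits <- with_genomes(hits, gene_map)
  present <- unique(c(hits$qgenome, hits$sgenome))
  for (g in c(genome_a, genome_b))
    if (!g %in% present)
      stop(sprintf("genome '%s' is absent from the hit table", g), call. = FALSE)
  keep <- hits$qgenome %in% c(genome_a, genome_b) &
    hits$sgenome %in% c(genome_a, genome_b)
  rbh_engine(hits[keep, , drop = FALSE], min_coverage, filter_order)
}

#' Reciprocal best hits for every genome pair in a hit table
#'
#' @inheritParams find_rbh
#' @return An `rbh_set` data.frame covering all unordered genome pairs.
#' @export
find_all_rbh <- function(hits, min_coverage = 0.70,
                         filter_order = c("before", "after"), gene_map = NULL) {
  assert_prob(min_coverage, "min_coverage")
  hits <- with_genomes(hits, gene_map)
  rbh_engine(hits, min_coverage, filter_order)
}

#' Build reference-anchored ortholog groups and their genome occupancy
#'
#' Groups are anchored on a designated reference genome (lexicographically
#' first by default): each reference gene defines a group containing its RBH
#' partner in every other genome. Occupancy is the fraction of genomes
#' represented; threshold 1.0 selects the core genome, 0.70 the Core-70 set
#' ("present in at least 70% of the genomes"), with membership count
#' `>= ceiling(threshold * n_genomes)`.
#'
#' @param rbh An `rbh_set` covering all genome pairs (see [find_all_rbh()]).
#' @param genomes Character vector of all genome IDs under analysis.
#' @param occupancy_threshold Minimum occupancy fraction, in \[0,1\].
#' @param reference Reference genome ID; default lexicographically first.
#' @param reference_genes Optional full gene inventory of the reference genome,
#'   so that reference genes without any RBH partner still yield (singleton)
#'   groups at threshold 0.
#' @return An `ortholog_groups` data.frame (family_id, genome_id, gene_id,
#'   occupancy), family_id being the anchoring reference gene.
#' @export
build_ortholog_groups <- function(rbh, genomes, occupancy_threshold = 1.0,
                                  reference = NULL, reference_genes = NULL) {
  assert_prob(occupancy_threshold, "occupancy_threshold")
  if (length(genomes) < 1) stop("no genomes given", call. = FALSE)
  genomes <- sort(unique(genomes))
  reference <- reference %||% genomes[1]
  if (!reference %in% genomes)
    stop(sprintf("reference genome '%s' is not among the genomes", reference),
         call. = FALSE)

  a_side <- rbh$genome_a == reference
  b_side <- rbh$genome_b == reference
  members <- data.frame(
    family_id = c(rbh$gene_a[a_side], rbh$gene_b[b_side]),
    genome_id = c(rbh$genome_b[a_side], rbh$genome_a[b_side]),
    gene_id = c(rbh$gene_b[a_side], rbh$gene_a[b_side]),
    stringsAsFactors = FALSE)
  anchors <- unique(c(members$family_id, reference_genes))
  members <- rbind(members,
                   data.frame(family_id = anchors, genome_id = reference,
                              gene_id = anchors, stringsAsFactors = FALSE))
  occ <- tapply(members$genome_id, members$family_id,
                function(g) length(unique(g))) / length(genomes)
  members$occupancy <- as.numeric(occ[members$family_id])
  need <- ceiling(occupancy_threshold * length(genomes))
  keep_fams <- names(occ)[occ * length(genomes) >= need]
  out <- members[members$family_id %in% keep_fams, ]
  out <- out[order(out$family_id, out$genome_id), ]
  rownames(out) <- NULL
  class(out) <- c("ortholog_groups", "data.frame")
  out
}

#' Genomic Similarity Score (GSS) matrix from RBH sets
#'
#' For genomes A and B, GSS(A,B) is the ratio of summed reciprocal bitscores
#' to summed self bitscores over their RBH pairs:
#' `sum(S(a->b) + S(b->a)) / sum(S(a->a) + S(b->b))`, defined as 0 when the
#' pair shares no RBHs. The score is symmetric, bounded in \[0,1\] and equals 1
#' for identical genomes; `1 - GSS` serves as the companion distance. This
#' ratio-of-summed-bitscores form is a documented approximation of the
#' published GSSa, which this package does not reproduce exactly.
#'
#' @param rbh An `rbh_set` with self-scores (see [find_all_rbh()]).
#' @param genomes Character vector of genome IDs for the matrix; defaults to
#'   the genomes present in `rbh`.
#' @return Symmetric numeric GSS matrix with unit diagonal.
#' @export
compute_gss <- function(rbh, genomes = NULL) {
  genomes <- sort(genomes %||% unique(c(rbh$genome_a, rbh$genome_b)))
  if (nrow(rbh) > 0) {
    if (anyNA(rbh$self_a) || anyNA(rbh$self_b))
      stop("self-scores missing for some RBH genes; hit table must contain self-hits",
           call. = FALSE)
    if (any(rbh$self_a <= 0) || any(rbh$self_b <= 0))
      stop("self-score must be > 0 for every gene in an RBH pair", call. = FALSE)
  }
  gss <- matrix(0, length(genomes), length(genomes),
                dimnames = list(genomes, genomes))
  if (nrow(rbh) > 0) {
    dt <- data.table::as.data.table(as.data.frame(rbh))
    agg <- dt[, list(num = sum(score_ab + score_ba),
                     den = sum(self_a + self_b)),
              by = c("genome_a", "genome_b")]
    v <- pmin(1, pmax(0, agg$num / agg$den))
    gss[cbind(agg$genome_a, agg$genome_b)] <- v
    gss[cbind(agg$genome_b, agg$genome_a)] <- v
  }
  diag(gss) <- 1
  gss
}

#' Distance matrix from a GSS matrix
#'
#' @param gss A GSS matrix from [compute_gss()].
#' @return `1 - GSS` with zero diagonal.
#' @export
gss_distance <- function(gss) {
  d <- 1 - gss
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}). Negative branch lengths,
#' which NJ can produce on non-additive input, are clamped to zero with the
#' deficit transferred to the sister branch so adjacent path lengths are
#' preserved (Phylip-compatible behaviour).
#'
#' @param dist Symmetric zero-diagonal distance matrix (or `dist`), >= 3 taxa.
#' @return An unrooted `phylo` tree with non-negative branch lengths.
#' @export
neighbor_joining <- function(dist) {
  d <- assert_distance_matrix(dist, "dist")
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  tree <- ape::nj(stats::as.dist(d))
  tol <- 1e-12
  for (pass in 1:10) {
    neg <- which(tree$edge.length < -tol)
    if (length(neg) == 0) break
    for (e in neg) {
      if (tree$edge.length[e] >= -tol) next
      parent <- tree$edge[e, 1]
      sibs <- setdiff(which(tree$edge[, 1] == parent), e)
      if (length(sibs) > 0)
        tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + tree$edge.length[e]
      tree$edge.length[e] <- 0
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
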