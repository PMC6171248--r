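# End-to-end orchestration: simulate (optionally), orthology -> GSS/NJ,
# profiles -> Jaccard -> clustering, association scan, adaptive functions,
# and tree congruence, with all stage tables persisted as TSV.

#' Pipeline configuration
#'
#' Collects input locations (or a simulation block) and the analysis
#' thresholds. Defaults are the method's reference values: 0.70 alignment
#' coverage for RBHs, 0.70 occupancy for Core-70, 0.70 PSSM coverage and 0.10
#' overlap for assignment filtering, cuts scanned from k = 3, alpha 0.05,
#' 0.80 presence gate for adaptive functions, support threshold 80.
#'
#' @param hits,gene_map,assignments,environments,reference_tree Input file
#'   paths (all but `reference_tree` required when `simulate` is NULL).
#' @param simulate Optional [simulation_config()]; when given, inputs are
#'   generated instead of read.
#' @param min_coverage RBH query-coverage threshold.
#' @param core_threshold Core-70 occupancy threshold.
#' @param min_pssm_coverage,max_overlap Assignment filter thresholds.
#' @param k_min,k_max,alpha Association-scan parameters.
#' @param min_presence Adaptive-function presence gate.
#' @param support_threshold Supported-node threshold.
#' @param linkage_methods Linkage methods to evaluate; the dendrogram with the
#'   highest agglomerative coefficient is carried forward.
#' @param seed Integer seed for any stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(hits = NULL, gene_map = NULL, assignments = NULL,
                            environments = NULL, reference_tree = NULL,
                            simulate = NULL,
                            min_coverage = 0.70, core_threshold = 0.70,
                            min_pssm_coverage = 0.70, max_overlap = 0.10,
                            k_min = 3, k_max = NULL, alpha = 0.05,
                            min_presence = 0.80, support_threshold = 80,
                            linkage_methods = c("ward", "average",
                                                "complete", "single"),
                            seed = 1L) {
  if (is.null(simulate)) {
    for (nm in c("hits", "gene_map", "assignments", "environments")) {
      v <- get(nm)
      if (is.null(v)) stop(sprintf("`%s` is required when no simulate block is given", nm),
                           call. = FALSE)
    }
  } else {
    stopifnot(inherits(simulate, "simulation_config"))
  }
  assert_prob(min_coverage, "min_coverage")
  assert_prob(core_threshold, "core_threshold")
  assert_prob(min_pssm_coverage, "min_pssm_coverage")
  assert_prob(max_overlap, "max_overlap")
  assert_count(k_min, "k_min", min = 2)
  if (!is.null(k_max)) assert_count(k_max, "k_max", min = 2)
  assert_prob(alpha, "alpha")
  assert_prob(min_presence, "min_presence")
  assert_nonneg(support_threshold, "support_threshold")
  linkage_methods <- match.arg(linkage_methods,
                               c("ward", "average", "complete", "single"),
                               several.ok = TRUE)
  assert_count(seed, "seed")
  structure(list(hits = hits, gene_map = gene_map, assignments = assignments,
                 environments = environments, reference_tree = reference_tree,
                 simulate = simulate, min_coverage = min_coverage,
                 core_threshold = core_threshold,
                 min_pssm_coverage = min_pssm_coverage,
                 max_overlap = max_overlap, k_min = as.integer(k_min),
                 k_max = if (is.null(k_max)) NULL else as.integer(k_max),
                 alpha = alpha, min_presence = min_presence,
                 support_threshold = support_threshold,
                 linkage_methods = linkage_methods, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Map environment labels outside the closed vocabulary to Unknown, warning.
normalize_environments <- function(env) {
  bad <- !env %in% environment_classes()
  if (any(bad)) {
    warning(sprintf("unknown environment classes mapped to Unknown: %s",
                    paste(unique(env[bad]), collapse = ", ")), call. = FALSE)
    env[bad] <- "Unknown"
  }
  env
}

write_tsv <- function(x, path, ...) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  path
}

#' Run the full gene-content convergence pipeline
#'
#' Executes: (optional) simulation of a fixture bundle; hit-table parsing and
#' all-pairs RBH with coverage filtering; core and Core-70 ortholog groups;
#' GSS matrix and neighbor-joining tree; assignment filtering and function
#' profiles; Jaccard distances; hierarchical clustering under every requested
#' linkage with the agglomerative coefficient deciding the dendrogram carried
#' forward; silhouettes at the k_min cut; the cluster-environment association
#' scan; adaptive-function detection on the k_min groups; and tree congruence
#' (RF matrix over the GSS-NJ tree, the reference/true tree when available,
#' and the content dendrogram, plus supported-node counts). All stage tables
#' are written to `outdir` as TSV/Newick with a deterministic run log; stage
#' progress goes to stderr.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, a report list with every intermediate object and the
#'   paths of the persisted artifacts.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(msg) message(sprintf("[convergene] %s", msg))
  paths <- list()

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    stage("simulating fixture bundle")
    manifest <- write_fixture_bundle(file.path(outdir, "sim"), config$simulate)
    objs <- attr(manifest, "objects")
    hits <- objs$hits
    hits <- with_genomes(hits)
    gene_map <- objs$genomes$gene_map[, c("gene_id", "genome_id")]
    env <- objs$env
    ref_tree <- objs$tree
    assignments <- utils::read.delim(file.path(outdir, "sim", "assignments.tsv"),
                                     stringsAsFactors = FALSE)
    truth <- manifest$planted
  } else {
    stage("reading inputs")
    gene_map <- utils::read.delim(config$gene_map, stringsAsFactors = FALSE)
    hits <- read_hit_table(config$hits, gene_map)
    envtab <- utils::read.delim(config$environments, stringsAsFactors = FALSE)
    env <- setNames(envtab$environment, envtab$genome_id)
    assignments <- utils::read.delim(config$assignments, stringsAsFactors = FALSE)
    ref_tree <- if (!is.null(config$reference_tree))
      read_newick(config$reference_tree) else NULL
    truth <- NULL
  }
  env <- normalize_environments(env)
  genomes <- sort(unique(gene_map$genome_id))

  # --- orthology / GSS / NJ -------------------------------------------------
  stage("computing reciprocal best hits")
  rbh <- find_all_rbh(hits, min_coverage = config$min_coverage)
  stage("building ortholog groups")
  ref_genes <- gene_map$gene_id[gene_map$genome_id == genomes[1]]
  groups_all <- build_ortholog_groups(rbh, genomes, occupancy_threshold = 0,
                                      reference_genes = ref_genes)
  occ <- tapply(groups_all$occupancy, groups_all$family_id, max)
  n_core <- sum(occ >= 1)
  need70 <- ceiling(config$core_threshold * length(genomes)) / length(genomes)
  n_core70 <- sum(occ >= need70)
  stage("computing GSS and neighbor-joining tree")
  gss <- compute_gss(rbh, genomes)
  gss_tree <- neighbor_joining(gss_distance(gss))

  # --- profiles / clustering ------------------------------------------------
  stage("building function profiles")
  filt <- filter_assignments(assignments,
                             min_pssm_coverage = config$min_pssm_coverage,
                             max_overlap = config$max_overlap)
  profiles <- build_profiles(filt, gene_map)
  jd <- profile_distance_matrix(profiles)

  stage("hierarchical clustering")
  dendrograms <- lapply(config$linkage_methods, function(m)
    hierarchical_cluster(jd, m))
  names(dendrograms) <- config$linkage_methods
  ac <- vapply(dendrograms, agglomerative_coefficient, numeric(1))
  best_method <- names(ac)[which.max(ac)]
  best <- dendrograms[[best_method]]
  part <- cut_dendrogram(best, config$k_min)
  sil <- silhouette_values(jd, part)

  # --- association / adaptive functions -------------------------------------
  stage("scanning cluster-environment associations")
  assoc <- scan_cluster_environment_associations(
    best, env, k_min = config$k_min, k_max = config$k_max, alpha = config$alpha)
  stage("detecting adaptive functions")
  adaptive <- find_adaptive_functions(profiles, part,
                                      min_presence = config$min_presence,
                                      alpha = config$alpha)

  # --- tree congruence ------------------------------------------------------
  stage("tree congruence")
  trees <- list(gss_nj = gss_tree)
  if (!is.null(ref_tree)) trees$reference <- ref_tree
  trees[[paste0("content_", best_method)]] <- mergetree_to_phylotree(best)
  congruence <- compare_trees_report(trees,
                                     support_threshold = config$support_threshold)

  # --- persist --------------------------------------------------------------
  stage("writing artifacts")
  paths$gss <- write_tsv(data.frame(genome_id = rownames(gss), gss,
                                    check.names = FALSE),
                         file.path(outdir, "gss.tsv"))
  paths$gss_tree <- write_newick(gss_tree, file.path(outdir, "gss_tree.nwk"))
  paths$groups <- write_tsv(as.data.frame(groups_all),
                            file.path(outdir, "ortholog_groups.tsv"))
  paths$profiles <- write_tsv(
    data.frame(genome_id = rep(names(profiles), lengths(profiles)),
               function_id = unlist(profiles, use.names = FALSE)),
    file.path(outdir, "profiles.tsv"))
  paths$jaccard <- write_tsv(data.frame(genome_id = rownames(jd), jd,
                                        check.names = FALSE),
                             file.path(outdir, "jaccard_distance.tsv"))
  merges <- do.call(rbind, lapply(names(dendrograms), function(m) {
    hc <- dendrograms[[m]]
    data.frame(method = m, step = seq_along(hc$height),
               left = hc$merge[, 1], right = hc$merge[, 2],
               height = hc$height)
  }))
  paths$merges <- write_tsv(merges, file.path(outdir, "merge_trees.tsv"))
  paths$content_tree <- write_newick(trees[[paste0("content_", best_method)]],
                                     file.path(outdir, "content_dendrogram.nwk"))
  paths$partition <- write_tsv(
    data.frame(genome_id = names(part), cluster = unname(part),
               silhouette = unname(sil[names(part)])),
    file.path(outdir, "partition.tsv"))
  paths$assoc <- write_tsv(as.data.frame(assoc),
                           file.path(outdir, "associations.tsv"))
  paths$adaptive <- write_tsv(as.data.frame(adaptive),
                              file.path(outdir, "adaptive_functions.tsv"))
  paths$rf <- write_tsv(data.frame(tree = rownames(congruence$rf),
                                   congruence$rf, check.names = FALSE),
                        file.path(outdir, "rf_matrix.tsv"))
  paths$supported <- write_tsv(
    data.frame(tree = names(congruence$supported),
               supported_nodes = unname(congruence$supported)),
    file.path(outdir, "supported_nodes.tsv"))

  log_lines <- c(
    sprintf("convergene %s", as.character(utils::packageVersion("convergene"))),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    sprintf("seed: %d", config$seed),
    sprintf("genomes: %d", length(genomes)),
    sprintf("min_coverage: %g; core_threshold: %g; min_pssm_coverage: %g; max_overlap: %g",
            config$min_coverage, config$core_threshold,
            config$min_pssm_coverage, config$max_overlap),
    sprintf("k_min: %d; alpha: %g; min_presence: %g; support_threshold: %g",
            config$k_min, config$alpha, config$min_presence,
            config$support_threshold),
    sprintf("core groups: %d; core-%d groups: %d", n_core,
            round(100 * config$core_threshold), n_core70),
    sprintf("agglomerative coefficients: %s",
            paste(sprintf("%s=%.4f", names(ac), ac), collapse = ", ")),
    sprintf("best linkage: %s", best_method),
    sprintf("last significant k: %s",
            as.character(attr(assoc, "last_significant_k"))))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  paths$log <- file.path(outdir, "run_log.txt")

  summary_md <- c(
    "# convergene run summary", "",
    sprintf("- genomes: %d", length(genomes)),
    sprintf("- ortholog groups: %d (core %d, occupancy >= %g: %d)",
            length(occ), n_core, config$core_threshold, n_core70),
    sprintf("- best dendrogram: %s linkage (agglomerative coefficient %.4f)",
            best_method, max(ac)),
    sprintf("- significant cluster-environment rows: %d",
            sum(assoc$significant %||% FALSE)),
    sprintf("- adaptive functions reported: %d", nrow(adaptive)),
    "", "See TSV artifacts for full tables.")
  writeLines(summary_md, file.path(outdir, "summary.md"))
  paths$summary <- file.path(outdir, "summary.md")

  invisible(list(
    genomes = genomes, env = env, rbh = rbh, ortholog_groups = groups_all,
    occupancy = occ, n_core = n_core, n_core70 = n_core70,
    gss = gss, gss_tree = gss_tree, profiles = profiles, jaccard = jd,
    dendrograms = dendrograms, agglomerative_coefficients = ac,
    best_method = best_method, partition = part, silhouettes = sil,
    associations = assoc, adaptive = adaptive, trees = trees,
    congruence = congruence, truth = truth, paths = paths, config = config))
}

#' Tree congruence report
#'
#' Square Robinson-Foulds symmetric-difference matrix over a set of named
#' trees sharing one leaf set, plus the per-tree count of well-supported
#' internal nodes.
#'
#' @param trees Named list of `phylo` trees.
#' @param support_threshold Inclusive support threshold for node counting.
#' @return List with `rf` (named integer matrix, zero diagonal) and
#'   `supported` (named integer vector).
#' @export
compare_trees_report <- function(trees, support_threshold = 80) {
  stopifnot(is.list(trees), length(trees) >= 1,
            all(vapply(trees, inherits, logical(1), "phylo")))
  if (is.null(names(trees)) || any(names(trees) == ""))
    names(trees) <- paste0("tree", seq_along(trees))
  n <- length(trees)
  rf <- matrix(0L, n, n, dimnames = list(names(trees), names(trees)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      v <- robinson_foulds(trees[[i]], trees[[j]])
      rf[i, j] <- v; rf[j, i] <- v
    }
  }
  supported <- vapply(trees, count_supported_nodes, integer(1),
                      threshold = support_threshold)
  list(rf = rf, supported = supported)
}
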