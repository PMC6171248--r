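# Simulation of gene-content evolution on a phylogeny with environment-driven
# convergent gene gain. The simulator provides planted ground truth (pool
# memberships, reassigned tips, the generating tree) so that every downstream
# stage -- orthology, clustering, association, congruence -- can be tested for
# recovery of known signal.

#' Closed vocabulary of environment classes
#'
#' Genomes are labelled with one of five isolation-environment classes:
#' Aquatic, Terrestrial, Facultative, Specialized, Unknown.
#' @return Character vector of the five class names.
#' @export
environment_classes <- function() {
  c("Aquatic", "Terrestrial", "Facultative", "Specialized", "Unknown")
}

#' Simulation configuration
#'
#' Bundles and validates all simulator parameters. The defaults describe the
#' package's reference in-silico study: 60 genomes in 3 environments with
#' polyphyletic environment membership (3 tips per environment reassigned
#' across clades), a core of 150 universal gene families, a deliberately weak
#' vertical accessory signal (50 ancestral accessory families, gain rate 0.5
#' and loss rate 0.5 per unit branch length), and strong environment-specific
#' gene pools (30 families per environment, each acquired by a member tip with
#' probability 0.9) emulating convergent lateral transfer.
#'
#' @param n_genomes Number of genomes (tree tips), >= 2.
#' @param n_environments Number of environment classes used, 1..5 (the class
#'   vocabulary is closed, see [environment_classes()]).
#' @param polyphyly_events Tips reassigned into each environment from other
#'   clades, making environments polyphyletic.
#' @param core_size Universal gene families, never lost.
#' @param ancestral_accessory Accessory families present in the root genome.
#' @param gain_rate Poisson rate of novel-family gains per unit branch length
#'   (infinitely-many-genes model: each gain is a brand-new family).
#' @param loss_rate Per-family loss rate; an accessory family present at the
#'   top of a branch of length l survives it with probability exp(-loss_rate*l).
#' @param pool_size Families in each environment's transfer pool. Pools are
#'   disjoint across environments and disjoint from vertically evolved families.
#' @param pool_gain_prob Probability that a tip acquires each family of its
#'   environment's pool.
#' @param bitscore_decay Exponential decay rate of cross-genome bitscores with
#'   patristic distance: score = self_score * exp(-bitscore_decay * d).
#' @param noise_sd Gaussian noise (bitscore units) added to cross-genome hits.
#' @param coverage_floor Alignment-coverage threshold the analysis will apply;
#'   recorded here so the fixture can place hits on both sides of it.
#' @param low_coverage_frac Fraction of gene families whose alignments fall
#'   below `coverage_floor` (drawn family-wise so that occupancy structure,
#'   including the core, remains well defined).
#' @param spurious_rate Fraction (relative to true cross hits) of spurious
#'   low-score cross-family hits, exercising best-hit tie-breaking.
#' @param birth_rate Speciation rate of the pure-birth tree.
#' @param seed Master seed; split internally into per-stage substreams.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genomes = 60,
                              n_environments = 3,
                              polyphyly_events = 3,
                              core_size = 150,
                              ancestral_accessory = 50,
                              gain_rate = 0.5,
                              loss_rate = 0.5,
                              pool_size = 30,
                              pool_gain_prob = 0.9,
                              bitscore_decay = 0.1,
                              noise_sd = 5,
                              coverage_floor = 0.70,
                              low_coverage_frac = 0.10,
                              spurious_rate = 0.01,
                              birth_rate = 1,
                              seed = 1L) {
  assert_count(n_genomes, "n_genomes", min = 2)
  assert_count(n_environments, "n_environments", min = 1)
  if (n_environments > length(environment_classes()))
    stop("`n_environments` cannot exceed the closed class vocabulary (5)",
         call. = FALSE)
  assert_count(polyphyly_events, "polyphyly_events")
  assert_count(core_size, "core_size")
  assert_count(ancestral_accessory, "ancestral_accessory")
  assert_count(pool_size, "pool_size")
  assert_nonneg(gain_rate, "gain_rate")
  assert_nonneg(loss_rate, "loss_rate")
  assert_prob(pool_gain_prob, "pool_gain_prob")
  assert_nonneg(bitscore_decay, "bitscore_decay")
  assert_nonneg(noise_sd, "noise_sd")
  assert_prob(coverage_floor, "coverage_floor")
  assert_prob(low_coverage_frac, "low_coverage_frac")
  assert_prob(spurious_rate, "spurious_rate")
  if (birth_rate <= 0) stop("`birth_rate` must be > 0", call. = FALSE)
  assert_count(seed, "seed")
  structure(list(
    n_genomes = as.integer(n_genomes),
    n_environments = as.integer(n_environments),
    polyphyly_events = as.integer(polyphyly_events),
    core_size = as.integer(core_size),
    ancestral_accessory = as.integer(ancestral_accessory),
    gain_rate = gain_rate, loss_rate = loss_rate,
    pool_size = as.integer(pool_size), pool_gain_prob = pool_gain_prob,
    bitscore_decay = bitscore_decay, noise_sd = noise_sd,
    coverage_floor = coverage_floor, low_coverage_frac = low_coverage_frac,
    spurious_rate = spurious_rate, birth_rate = birth_rate,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; identical `(n_tips, seed, birth_rate)` reproduce
#'   the tree exactly.
#' @param birth_rate Speciation rate (> 0).
#' @return A rooted binary `phylo` tree with tips labelled `g01`, `g02`, ...
#' @export
simulate_tree <- function(n_tips, seed, birth_rate = 1) {
  assert_count(n_tips, "n_tips", min = 2)
  if (birth_rate <= 0) stop("`birth_rate` must be > 0", call. = FALSE)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  w <- max(2L, nchar(as.character(n_tips)))
  tree$tip.label <- sprintf(paste0("g%0", w, "d"), seq_len(n_tips))
  tree
}

#' Assign environment labels to tree tips with controlled polyphyly
#'
#' Environments are first assigned clade-wise: the tree is cut into
#' `n_environments` subtrees (repeatedly splitting the largest group at its
#' root) and each subtree gets one environment class, so every environment
#' starts monophyletic. Then, for each environment, `polyphyly_events` tips
#' currently carrying another label are reassigned into it, making the
#' environments polyphyletic the way convergently adapted lineages are.
#'
#' @param tree A `phylo` tree.
#' @param n_environments Number of classes to use (1..5, <= number of tips).
#' @param polyphyly_events Tips reassigned into each environment.
#' @param seed Integer seed.
#' @return Named character vector (tip -> environment class) with attributes
#'   `reassigned` (tips moved across clades) and `clade_partition` (the
#'   original monophyletic assignment as a named integer vector).
#' @export
assign_environments <- function(tree, n_environments, polyphyly_events, seed) {
  stopifnot(inherits(tree, "phylo"))
  n_tips <- length(tree$tip.label)
  assert_count(n_environments, "n_environments", min = 1)
  if (n_environments > n_tips)
    stop("`n_environments` cannot exceed the number of tips", call. = FALSE)
  if (n_environments > length(environment_classes()))
    stop("`n_environments` cannot exceed the closed class vocabulary (5)",
         call. = FALSE)
  assert_count(polyphyly_events, "polyphyly_events")

  tips_of <- function(node) {
    if (node <= n_tips) return(node)
    unlist(phangorn::Descendants(tree, node, type = "tips"))
  }
  children_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]

  groups <- list(n_tips + 1L)  # start from the root
  while (length(groups) < n_environments) {
    sizes <- vapply(groups, function(nd) length(tips_of(nd)), integer(1))
    splittable <- which(sizes > 1L)
    pick <- splittable[which.max(sizes[splittable])]
    groups <- c(groups[-pick], as.list(children_of(groups[[pick]])))
  }
  tip_sets <- lapply(groups, tips_of)
  ord <- order(vapply(tip_sets, length, integer(1)), decreasing = TRUE)
  tip_sets <- tip_sets[ord]

  env <- setNames(character(n_tips), tree$tip.label)
  classes <- environment_classes()[seq_len(n_environments)]
  clade_partition <- setNames(integer(n_tips), tree$tip.label)
  for (i in seq_along(tip_sets)) {
    env[tip_sets[[i]]] <- classes[i]
    clade_partition[tip_sets[[i]]] <- i
  }

  reassigned <- character(0)
  if (n_environments >= 2 && polyphyly_events > 0) {
    env <- with_seed(seed, {
      for (e in classes) {
        candidates <- setdiff(names(env)[env != e], reassigned)
        take <- sample(candidates, min(polyphyly_events, length(candidates)))
        env[take] <- e
        reassigned <- c(reassigned, take)
      }
      env
    })
  }
  structure(env, reassigned = reassigned, clade_partition = clade_partition)
}

#' Evolve gene content along a phylogeny with environment pools
#'
#' The root genome carries `core_size` universal families plus
#' `ancestral_accessory` accessory families. Along each branch of length `l`,
#' `Poisson(gain_rate * l)` brand-new families are gained (infinitely-many-genes
#' model) and each present accessory family is lost with probability
#' `1 - exp(-loss_rate * l)`; core families are never lost. At each tip, every
#' family of the tip environment's pool is acquired independently with
#' probability `pool_gain_prob`. Pools are disjoint across environments and
#' disjoint from all vertically evolved families, so convergent signal has an
#' unambiguous planted truth.
#'
#' @param tree A `phylo` tree.
#' @param envmap Named environment vector as from [assign_environments()].
#' @param config A [simulation_config()].
#' @return A `genome_set`: list with `genomes` (IDs), `profiles` (per-genome
#'   family sets), `gene_map` (data.frame gene_id/genome_id/family_id; gene IDs
#'   follow the `genome|gene` convention) and `pools` (environment -> planted
#'   family IDs).
#' @export
evolve_gene_content <- function(tree, envmap, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "simulation_config"))
  if (!setequal(tree$tip.label, names(envmap)))
    stop("tree tips and environment map keys do not match", call. = FALSE)

  n_tips <- length(tree$tip.label)
  core <- if (config$core_size > 0) sprintf("C%04d", seq_len(config$core_size)) else character(0)
  anc <- if (config$ancestral_accessory > 0)
    sprintf("A%04d", seq_len(config$ancestral_accessory)) else character(0)
  classes <- sort(unique(unname(envmap)))
  pools <- lapply(classes, function(e)
    if (config$pool_size > 0) sprintf("P%s_%03d", e, seq_len(config$pool_size)) else character(0))
  names(pools) <- classes

  tr <- stats::reorder(tree, "cladewise")
  states <- vector("list", n_tips + tr$Nnode)
  states[[n_tips + 1L]] <- c(core, anc)

  profiles <- with_seed(stage_seed(config$seed, 3), {
    for (i in seq_len(nrow(tr$edge))) {
      u <- tr$edge[i, 1]; v <- tr$edge[i, 2]; len <- tr$edge.length[i]
      acc <- setdiff(states[[u]], core)
      kept <- acc[stats::runif(length(acc)) < exp(-config$loss_rate * len)]
      n_gain <- stats::rpois(1, config$gain_rate * len)
      gains <- if (n_gain > 0) sprintf("N%d_%03d", v, seq_len(n_gain)) else character(0)
      states[[v]] <- c(core, kept, gains)
    }
    prof <- vector("list", n_tips)
    names(prof) <- tr$tip.label
    for (t in seq_len(n_tips)) {
      pool <- pools[[envmap[[tr$tip.label[t]]]]]
      acquired <- pool[stats::runif(length(pool)) < config$pool_gain_prob]
      prof[[t]] <- sort(unique(c(states[[t]], acquired)))
    }
    prof
  })

  genomes <- sort(tree$tip.label)
  profiles <- profiles[genomes]
  gene_map <- data.frame(
    gene_id = unlist(lapply(genomes, function(g)
      paste0(g, "|", sprintf("p%05d", seq_along(profiles[[g]])))), use.names = FALSE),
    genome_id = rep(genomes, lengths(profiles)),
    family_id = unlist(profiles, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  structure(list(genomes = genomes, profiles = profiles,
                 gene_map = gene_map, pools = pools),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("genome_set: %d genomes, %d gene families, %d genes\n",
              length(x$genomes), length(unique(x$gene_map$family_id)),
              nrow(x$gene_map)))
  invisible(x)
}

# Per-family alignment attributes (self score, protein length, base alignment
# coverage). Drawn in their own substream so the hit table and the assignment
# table see identical family properties.
family_attributes <- function(families, config) {
  with_seed(stage_seed(config$seed, 6), {
    n <- length(families)
    self_score <- stats::runif(n, 200, 800)
    low <- stats::runif(n) < config$low_coverage_frac
    cov_base <- ifelse(low, stats::runif(n, 0.40, 0.69), stats::runif(n, 0.78, 0.98))
    data.frame(family_id = families,
               self_score = self_score,
               length = pmax(50L, as.integer(round(self_score / 1.9))),
               cov_base = cov_base,
               low_coverage = low,
               stringsAsFactors = FALSE)
  })
}

#' Synthesize an all-vs-all hit table from simulated gene content
#'
#' Stands in for all-vs-all BLAST: for every genome pair and every shared
#' family, reciprocal directed hits are emitted with
#' `bitscore = self_score * exp(-bitscore_decay * d) + N(0, noise_sd)` where
#' `d` is the patristic distance between the genomes. Self-hits are emitted at
#' the self score with full coverage. Alignment coverage is drawn around a
#' per-family base value, a `low_coverage_frac` share of families falling below
#' the analysis coverage floor. A `spurious_rate` fraction of low-score
#' cross-family hits exercises best-hit tie-breaking.
#'
#' @param genomes A `genome_set` from [evolve_gene_content()].
#' @param tree The generating `phylo` tree.
#' @param config The [simulation_config()] used to generate `genomes`.
#' @return A `hit_table` data.frame in 13-column BLAST tabular dialect
#'   (outfmt 6 plus `qcovs`, query coverage as a fraction).
#' @export
synthesize_hit_table <- function(genomes, tree, config) {
  stopifnot(inherits(genomes, "genome_set"), inherits(tree, "phylo"),
            inherits(config, "simulation_config"))
  gm <- data.table::as.data.table(genomes$gene_map)
  fam <- family_attributes(sort(unique(gm$family_id)), config)
  famdt <- data.table::as.data.table(fam)
  D <- stats::cophenetic(tree)

  hit_rows <- function(qid, sid, pident, len, evalue, bits, qcov) {
    data.table::data.table(
      qseqid = qid, sseqid = sid,
      pident = round(pident, 2), length = as.integer(len),
      mismatch = as.integer(round(len * (1 - pident / 100))),
      gapopen = 0L, qstart = 1L, qend = as.integer(len),
      sstart = 1L, send = as.integer(len),
      evalue = signif(evalue, 3), bitscore = round(bits, 1),
      qcovs = round(qcov, 3))
  }

  with_seed(stage_seed(config$seed, 4), {
    # self hits
    self <- merge(gm, famdt, by = "family_id")
    self_hits <- hit_rows(self$gene_id, self$gene_id, 100, self$length,
                          pmax(self$length * 2^(-self$self_score), 0),
                          self$self_score, 1)

    # reciprocal cross hits: one gene per family per genome, so a family-wise
    # self-join yields every ordered genome pair sharing the family
    cross <- merge(gm, gm, by = "family_id", allow.cartesian = TRUE,
                   suffixes = c("", ".s"))
    cross <- cross[cross$genome_id != cross$genome_id.s, ]
    cross <- merge(cross, famdt, by = "family_id")
    d <- D[cbind(cross$genome_id, cross$genome_id.s)]
    n <- nrow(cross)
    bits <- pmax(cross$self_score * exp(-config$bitscore_decay * d) +
                   stats::rnorm(n, 0, config$noise_sd), 2)
    cov <- pmin(1, pmax(0, cross$cov_base + stats::runif(n, -0.03, 0.03)))
    pid <- pmax(15, pmin(100, 100 * exp(-0.08 * d) + stats::rnorm(n, 0, 1)))
    len <- pmax(1, round(cov * cross$length))
    cross_hits <- hit_rows(cross$gene_id, cross$gene_id.s, pid, len,
                           pmax(cross$length * 2^(-bits), 0), bits, cov)

    # spurious low-score cross-family hits
    n_sp <- round(config$spurious_rate * n)
    if (n_sp > 0 && nrow(gm) > 1) {
      qi <- sample.int(nrow(gm), n_sp, replace = TRUE)
      si <- sample.int(nrow(gm), n_sp, replace = TRUE)
      ok <- gm$family_id[qi] != gm$family_id[si] & gm$gene_id[qi] != gm$gene_id[si]
      qi <- qi[ok]; si <- si[ok]
      if (length(qi) > 0) {
        lensp <- pmax(20, round(stats::runif(length(qi), 0.3, 0.95) * 150))
        sp_hits <- hit_rows(gm$gene_id[qi], gm$gene_id[si],
                            stats::runif(length(qi), 20, 35), lensp,
                            stats::runif(length(qi), 1e-4, 10),
                            stats::runif(length(qi), 25, 45),
                            stats::runif(length(qi), 0.30, 0.95))
      } else sp_hits <- NULL
    } else sp_hits <- NULL

    out <- data.table::rbindlist(Filter(Negate(is.null),
                                        list(self_hits, cross_hits, sp_hits)))
    data.table::setorder(out, qseqid, sseqid, -bitscore)
    out <- as.data.frame(out)
    class(out) <- c("hit_table", "data.frame")
    out
  })
}

#' Write a complete simulated fixture bundle
#'
#' Generates a phylogeny, environment labels, gene content, hit table and
#' function-assignment table under one configuration and writes them, together
#' with a JSON manifest recording the configuration, per-file MD5 checksums and
#' the planted truths (environment pool families, reassigned tips, the original
#' clade partition).
#'
#' @param outdir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`). The simulated objects are attached as attribute
#'   `objects` for programmatic use.
#' @export
write_fixture_bundle <- function(outdir, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop(sprintf("cannot create output directory '%s'", outdir), call. = FALSE)

  tree <- simulate_tree(config$n_genomes, stage_seed(config$seed, 1), config$birth_rate)
  env <- assign_environments(tree, config$n_environments,
                             config$polyphyly_events, stage_seed(config$seed, 2))
  gs <- evolve_gene_content(tree, env, config)
  hits <- synthesize_hit_table(gs, tree, config)

  fam <- family_attributes(sort(unique(gs$gene_map$family_id)), config)
  assignments <- with_seed(stage_seed(config$seed, 5), {
    a <- merge(gs$gene_map, fam, by = "family_id", sort = FALSE)
    data.frame(protein_id = a$gene_id,
               function_id = a$family_id,
               score = round(a$self_score + stats::rnorm(nrow(a), 0, 5), 1),
               pssm_coverage = round(stats::runif(nrow(a), 0.80, 1.00), 3),
               qstart = 1L,
               qend = as.integer(round(a$length * 0.95)),
               stringsAsFactors = FALSE)
  })
  assignments <- assignments[order(assignments$protein_id), ]

  families <- sort(unique(gs$gene_map$family_id))
  pm <- t(vapply(gs$genomes, function(g)
    as.integer(families %in% gs$profiles[[g]]), integer(length(families))))
  colnames(pm) <- families

  paths <- file.path(outdir, c(
    tree = "tree.nwk", environments = "environments.tsv",
    presence = "presence_matrix.tsv", hits = "hits.tsv",
    gene_map = "gene_map.tsv", assignments = "assignments.tsv"))
  names(paths) <- c("tree", "environments", "presence", "hits",
                    "gene_map", "assignments")

  write_newick(tree, paths[["tree"]])
  utils::write.table(
    data.frame(genome_id = names(env), environment = unname(env)),
    paths[["environments"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(genome_id = rownames(pm), pm, check.names = FALSE),
    paths[["presence"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_hit_table(hits, paths[["hits"]])
  utils::write.table(gs$gene_map[, c("gene_id", "genome_id")],
                     paths[["gene_map"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(assignments, paths[["assignments"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    config = unclass(config),
    files = as.list(unname(tools::md5sum(paths))),
    planted = list(pools = gs$pools,
                   reassigned_tips = attr(env, "reassigned"),
                   clade_partition = as.list(attr(env, "clade_partition"))))
  names(manifest$files) <- basename(paths)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "objects") <- list(tree = tree, env = env, genomes = gs, hits = hits)
  invisible(manifest)
}
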