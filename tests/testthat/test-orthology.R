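test_that("hit tables round-trip through write/read and reject malformed input", {
  hits <- tiny_hits()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, path)
  back <- read_hit_table(path)
  expect_equal(as.data.frame(back)[names(hits)], as.data.frame(hits),
               ignore_attr = TRUE)
  expect_equal(back$qgenome, sub("\\|.*", "", hits$qseqid))

  # empty file -> empty table
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(read_hit_table(empty)), 0)

  # 12 columns -> parse error naming column 13
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(rep("1", 12), collapse = "\t"), bad)
  expect_error(read_hit_table(bad), "column 13.*qcovs|qcovs")

  # negative bitscore -> validation error
  neg <- hits; neg$bitscore[1] <- -5
  negp <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(neg, negp)
  expect_error(read_hit_table(negp), "negative bitscore")
})

test_that("find_rbh applies the coverage filter and mutual-best reciprocity", {
  hits <- tiny_hits()
  rbh <- find_rbh(hits, "A", "B", min_coverage = 0.70)

  # a1/b1: best both ways at coverage 0.9 -> kept
  expect_true(any(rbh$gene_a == "A|a1" & rbh$gene_b == "B|b1"))
  # a2/b2: best both ways but a2->b2 coverage 0.65 < 0.70 -> excluded
  expect_false(any(rbh$gene_a == "A|a2" & rbh$gene_b == "B|b2"))
  # a3's best is b3, but b3's best is a2 -> no pair for a3
  expect_false(any(rbh$gene_a == "A|a3"))
  expect_equal(nrow(rbh), 1)

  # self-scores carried for GSS
  expect_equal(rbh$self_a, 400)
  expect_equal(rbh$self_b, 395)

  # symmetry: find_rbh(A,B) == find_rbh(B,A)
  expect_identical(rbh, find_rbh(hits, "B", "A", min_coverage = 0.70))

  # exactly at the floor is kept ("at least 70%")
  at_floor <- hits
  at_floor$qcovs[at_floor$qseqid == "A|a2" & at_floor$sseqid == "B|b2"] <- 0.70
  rbh70 <- find_rbh(at_floor, "A", "B", min_coverage = 0.70)
  expect_true(any(rbh70$gene_a == "A|a2" & rbh70$gene_b == "B|b2"))

  expect_error(find_rbh(hits, "A", "Z"), "absent")
})

test_that("raising min_coverage never adds RBH pairs", {
  cfg <- small_sim_config(seed = 3)
  tree <- simulate_tree(cfg$n_genomes, seed = 30)
  env <- assign_environments(tree, 3, 1, seed = 30)
  gs <- evolve_gene_content(tree, env, cfg)
  hits <- synthesize_hit_table(gs, tree, cfg)
  prev <- NULL
  for (mc in c(0, 0.5, 0.7, 0.9)) {
    rbh <- find_all_rbh(hits, min_coverage = mc)
    keys <- paste(rbh$gene_a, rbh$gene_b)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("ortholog groups respect occupancy thresholds and nest", {
  # 3 genomes; family f in all three (mutual RBHs), family h in 2 of 3
  rbh <- data.frame(
    genome_a = c("A", "A", "B", "A"),
    genome_b = c("B", "C", "C", "B"),
    gene_a   = c("A|f", "A|f", "B|f", "A|h"),
    gene_b   = c("B|f", "C|f", "C|f", "B|h"),
    score_ab = 100, score_ba = 100, self_a = 150, self_b = 150,
    stringsAsFactors = FALSE)
  genomes <- c("A", "B", "C")

  core <- build_ortholog_groups(rbh, genomes, occupancy_threshold = 1.0)
  expect_setequal(unique(core$family_id), "A|f")
  expect_equal(unique(core$occupancy[core$family_id == "A|f"]), 1)

  # occupancy 2/3 < 0.70 (ceil(0.7*3) = 3 members required): h excluded
  core70 <- build_ortholog_groups(rbh, genomes, occupancy_threshold = 0.70)
  expect_setequal(unique(core70$family_id), "A|f")

  all_groups <- build_ortholog_groups(rbh, genomes, occupancy_threshold = 0,
                                      reference_genes = c("A|f", "A|h", "A|z"))
  expect_setequal(unique(all_groups$family_id), c("A|f", "A|h", "A|z"))
  expect_equal(unique(all_groups$occupancy[all_groups$family_id == "A|h"]), 2 / 3)

  # nesting: core <= core70 <= all
  expect_true(all(unique(core$family_id) %in% unique(core70$family_id)))
  expect_true(all(unique(core70$family_id) %in% unique(all_groups$family_id)))
})

test_that("core/Core-70 nesting holds on simulated data", {
  cfg <- small_sim_config(seed = 8, ancestral_accessory = 40, loss_rate = 0.1)
  tree <- simulate_tree(cfg$n_genomes, seed = 80)
  env <- assign_environments(tree, 3, 1, seed = 80)
  gs <- evolve_gene_content(tree, env, cfg)
  hits <- synthesize_hit_table(gs, tree, cfg)
  rbh <- find_all_rbh(hits, 0.70)
  core <- unique(build_ortholog_groups(rbh, gs$genomes, 1.0)$family_id)
  core70 <- unique(build_ortholog_groups(rbh, gs$genomes, 0.70)$family_id)
  expect_gt(length(core), 0)
  expect_true(all(core %in% core70))
  expect_gt(length(core70), length(core))
})

test_that("GSS follows the summed-bitscore ratio with its boundary conventions", {
  one <- data.frame(genome_a = "A", genome_b = "B", gene_a = "A|x",
                    gene_b = "B|x", score_ab = 50, score_ba = 50,
                    self_a = 100, self_b = 100, stringsAsFactors = FALSE)
  g <- compute_gss(one, genomes = c("A", "B", "C"))
  expect_equal(g["A", "B"], (50 + 50) / (100 + 100))  # 0.5 by substitution
  expect_equal(g["A", "C"], 0)                         # no RBHs -> 0
  expect_equal(unname(diag(g)), c(1, 1, 1))
  expect_equal(g, t(g))
  d <- gss_distance(g)
  expect_equal(d["A", "B"], 0.5)
  expect_equal(d["A", "C"], 1)
  expect_equal(unname(diag(d)), c(0, 0, 0))

  # identical genomes: every cross score equals the self score -> GSS 1
  ident <- data.frame(genome_a = "A", genome_b = "B",
                      gene_a = c("A|1", "A|2"), gene_b = c("B|1", "B|2"),
                      score_ab = c(100, 80), score_ba = c(100, 80),
                      self_a = c(100, 80), self_b = c(100, 80),
                      stringsAsFactors = FALSE)
  expect_equal(compute_gss(ident)["A", "B"], 1)

  bad <- one; bad$self_a <- 0
  expect_error(compute_gss(bad), "self-score")
})

test_that("neighbor joining recovers additive trees exactly", {
  # hand-checkable 4-taxon additive matrix from ((A:0.1,B:0.2):0.1,C:0.3,D:0.4)
  d <- matrix(c(0, 0.3, 0.5, 0.6,
                0.3, 0, 0.6, 0.7,
                0.5, 0.6, 0, 0.7,
                0.6, 0.7, 0.7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  truth <- ape::read.tree(text = "((A:0.1,B:0.2):0.1,C:0.3,D:0.4);")
  expect_equal(robinson_foulds(tr, truth), 0)      # AB|CD recovered
  expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)                   # exact branch lengths

  # 3 taxa: closed-form three-point lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(d3)
  cp <- stats::cophenetic(t3)[rownames(d3), colnames(d3)]
  expect_equal(cp, d3, tolerance = 1e-10)

  # ultrametric two well-separated pairs: the pairs are cherries
  d4 <- matrix(10, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d4) <- 0; d4["a", "b"] <- d4["b", "a"] <- 1; d4["c", "d"] <- d4["d", "c"] <- 1
  t4 <- neighbor_joining(d4)
  expect_equal(robinson_foulds(t4, ape::read.tree(text = "((a,b),(c,d));")), 0)

  asym <- d; asym[1, 2] <- 0.9
  expect_error(neighbor_joining(asym), "symmetric")
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("NJ returns the generating topology for random additive matrices", {
  set.seed(71)
  for (i in 1:30) {
    case <- random_additive_case(sample(4:10, 1))
    tr <- neighbor_joining(case$d)
    expect_equal(robinson_foulds(tr, case$tree), 0)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("negative NJ branches are clamped with sister compensation", {
  # a non-additive matrix known to drive an NJ branch negative
  d <- matrix(c(0, 1, 10, 9,
                1, 0, 12, 2,
                10, 12, 0, 11,
                9, 2, 11, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(stats::as.dist(d))
  expect_true(any(raw$edge.length < 0))  # the case actually exercises clamping
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  # total tree length preserved by the transfer
  expect_equal(sum(tr$edge.length), sum(raw$edge.length), tolerance = 1e-9)
})
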