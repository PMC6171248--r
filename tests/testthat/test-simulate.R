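test_that("simulate_tree produces deterministic binary trees of the right size", {
  expect_error(simulate_tree(1, seed = 1), "n_tips")

  t2 <- simulate_tree(2, seed = 4)
  expect_s3_class(t2, "phylo")
  expect_equal(length(t2$tip.label), 2)

  t8 <- simulate_tree(8, seed = 4)
  expect_equal(length(t8$tip.label), 8)
  expect_equal(t8$Nnode, 7)  # rooted binary: n - 1 internal nodes
  expect_true(all(t8$edge.length >= 0))

  expect_identical(write_newick(simulate_tree(8, seed = 11)),
                   write_newick(simulate_tree(8, seed = 11)))
  expect_false(identical(write_newick(simulate_tree(8, seed = 11)),
                         write_newick(simulate_tree(8, seed = 12))))
})

test_that("assign_environments is clade-wise, then reassigns the requested tips", {
  tree <- simulate_tree(20, seed = 3)

  # no polyphyly: every environment monophyletic
  env0 <- assign_environments(tree, 3, 0, seed = 5)
  expect_setequal(names(env0), tree$tip.label)
  expect_equal(length(unique(env0)), 3)
  for (e in unique(env0)) {
    tips <- names(env0)[env0 == e]
    if (length(tips) > 1) {
      mrca <- ape::getMRCA(tree, tips)
      clade <- ape::extract.clade(tree, mrca)$tip.label
      expect_setequal(clade, tips)
    }
  }

  # polyphyly events break monophyly for at least one environment
  env1 <- assign_environments(tree, 3, 2, seed = 5)
  reassigned <- attr(env1, "reassigned")
  expect_true(length(reassigned) >= 2)
  broken <- vapply(unique(env1), function(e) {
    tips <- names(env1)[env1 == e]
    if (length(tips) < 2) return(FALSE)
    clade <- ape::extract.clade(tree, ape::getMRCA(tree, tips))$tip.label
    !setequal(clade, tips)
  }, logical(1))
  expect_true(any(broken))
  # the original clade-wise partition is preserved as planted truth
  expect_setequal(names(attr(env1, "clade_partition")), tree$tip.label)

  # single environment: one label regardless of events
  envA <- assign_environments(tree, 1, 5, seed = 2)
  expect_equal(unname(unique(envA)), "Aquatic")

  expect_error(assign_environments(tree, 21, 0, seed = 1), "exceed")
})

test_that("gene content honours degenerate rate settings", {
  tree <- simulate_tree(10, seed = 9)
  env <- assign_environments(tree, 2, 1, seed = 9)

  # no gains, no losses, no pools: every tip equals the ancestral genome
  cfg0 <- simulation_config(n_genomes = 10, core_size = 20,
                            ancestral_accessory = 10, gain_rate = 0,
                            loss_rate = 0, pool_gain_prob = 0, seed = 9)
  gs0 <- evolve_gene_content(tree, env, cfg0)
  ancestral <- sort(c(sprintf("C%04d", 1:20), sprintf("A%04d", 1:10)))
  for (g in gs0$genomes) expect_identical(gs0$profiles[[g]], ancestral)

  # p_pool = 1: every tip carries its environment's entire pool
  cfg1 <- simulation_config(n_genomes = 10, core_size = 20,
                            ancestral_accessory = 10, pool_size = 6,
                            pool_gain_prob = 1, seed = 9)
  gs1 <- evolve_gene_content(tree, env, cfg1)
  for (g in gs1$genomes)
    expect_true(all(gs1$pools[[env[[g]]]] %in% gs1$profiles[[g]]))
})

test_that("core families are conserved in every tip at any loss rate", {
  tree <- simulate_tree(15, seed = 2)
  env <- assign_environments(tree, 3, 1, seed = 2)
  cfg <- simulation_config(n_genomes = 15, core_size = 25,
                           ancestral_accessory = 40, gain_rate = 2,
                           loss_rate = 3, seed = 2)
  gs <- evolve_gene_content(tree, env, cfg)
  core <- sprintf("C%04d", 1:25)
  for (g in gs$genomes) expect_true(all(core %in% gs$profiles[[g]]))
})

test_that("gain counts match the Poisson mean on replicate branches", {
  # 10,000 replicate branches of length 1.5 at gain rate 2: one star tree,
  # each pendant edge is an independent branch realization
  n <- 10000
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", seq_len(n), ":1.5", collapse = ","), ");"))
  env <- setNames(rep("Aquatic", n), star$tip.label)
  cfg <- simulation_config(n_genomes = n, core_size = 1,
                           ancestral_accessory = 0, gain_rate = 2,
                           loss_rate = 0, pool_size = 0, seed = 42)
  gs <- evolve_gene_content(star, env, cfg)
  gains <- lengths(gs$profiles) - 1  # minus the single core family
  lambda_l <- 2 * 1.5
  se <- sqrt(lambda_l / n)
  expect_lt(abs(mean(gains) - lambda_l), 3 * se)
})

test_that("synthetic hit tables decay with distance and keep self-hits on top", {
  cfg <- small_sim_config(noise_sd = 0, spurious_rate = 0)
  tree <- simulate_tree(cfg$n_genomes, seed = 21)
  env <- assign_environments(tree, 3, 1, seed = 21)
  gs <- evolve_gene_content(tree, env, cfg)
  hits <- synthesize_hit_table(gs, tree, cfg)
  expect_named(hits, c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore", "qcovs"))

  # self-hit strictly best for every gene
  best <- tapply(seq_len(nrow(hits)), hits$qseqid, function(i)
    hits$sseqid[i][which.max(hits$bitscore[i])])
  expect_true(all(best == names(best)))

  # for a fixed family, cross-genome bitscore non-increasing in patristic distance
  D <- stats::cophenetic(tree)
  cross <- hits[hits$qseqid != hits$sseqid, ]
  fam_of <- setNames(gs$gene_map$family_id, gs$gene_map$gene_id)
  gen_of <- setNames(gs$gene_map$genome_id, gs$gene_map$gene_id)
  cross <- cross[fam_of[cross$qseqid] == fam_of[cross$sseqid], ]
  fam <- names(sort(table(fam_of[cross$qseqid]), decreasing = TRUE))[1]
  sub <- cross[fam_of[cross$qseqid] == fam, ]
  d <- D[cbind(gen_of[sub$qseqid], gen_of[sub$sseqid])]
  ord <- order(d)
  expect_true(all(diff(sub$bitscore[ord]) <= 1e-9))

  # reciprocal partners in a shared family are each other's best cross hits
  g1 <- gs$genomes[1]
  shared <- intersect(gs$profiles[[g1]], gs$profiles[[gs$genomes[2]]])[1]
  genes <- gs$gene_map$gene_id[gs$gene_map$family_id == shared &
                                 gs$gene_map$genome_id %in% gs$genomes[1:2]]
  x <- cross[cross$qseqid == genes[1] & gen_of[cross$sseqid] == gs$genomes[2], ]
  expect_equal(x$sseqid[which.max(x$bitscore)], genes[2])
})

test_that("fixture bundles are complete, deterministic and record planted truth", {
  cfg <- small_sim_config(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(d1, cfg)
  m2 <- write_fixture_bundle(d2, cfg)

  expect_length(m1$files, 6)
  expect_true(all(file.exists(file.path(d1, names(m1$files)))))
  expect_identical(m1$files, m2$files)  # same seed -> identical checksums

  # every pool family's environment is retrievable
  pools <- m1$planted$pools
  expect_true(all(grepl("^PAquatic_", pools$Aquatic)))
  expect_equal(lengths(pools), setNames(rep(cfg$pool_size, 3),
                                        sort(names(pools))),
               ignore_attr = TRUE)

  # pool_size = 0 -> empty planted-adaptive list
  m0 <- write_fixture_bundle(withr::local_tempdir(),
                             small_sim_config(seed = 5, pool_size = 0))
  expect_equal(sum(lengths(m0$planted$pools)), 0)

  # different seed -> different content
  m3 <- write_fixture_bundle(withr::local_tempdir(),
                             small_sim_config(seed = 6))
  expect_false(identical(m1$files[["hits.tsv"]], m3$files[["hits.tsv"]]))
})

test_that("without pools, Jaccard similarity declines with patristic distance", {
  cors <- vapply(1:10, function(s) {
    cfg <- small_sim_config(seed = s, pool_gain_prob = 0,
                            ancestral_accessory = 30, gain_rate = 1)
    tree <- simulate_tree(cfg$n_genomes, convergene:::stage_seed(s, 1))
    env <- assign_environments(tree, 3, 1, convergene:::stage_seed(s, 2))
    gs <- evolve_gene_content(tree, env, cfg)
    jd <- profile_distance_matrix(gs$profiles)
    D <- stats::cophenetic(tree)[rownames(jd), colnames(jd)]
    lower <- lower.tri(jd)
    stats::cor(jd[lower], D[lower], method = "spearman")
  }, numeric(1))
  expect_gt(mean(cors), 0.5)  # Jd rises (J falls) with distance
  expect_true(all(cors > 0))
})
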