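# convergene

Detecting environmentally driven gene-content convergence against a
phylogenetic background.

## The problem

Bacterial lineages isolated from similar environments sometimes resemble each
other in gene content more than their phylogeny warrants — a signature of
convergent (homoplasic) lateral gene transfer. Distinguishing that signal
from vertical descent takes two parallel views of the same genomes:

* a **phylogenomic** view: orthologs as BLAST reciprocal best hits (RBHs),
  core / Core-70 gene sets, and a Genomic Similarity Score (GSS) tree, where

  `GSS(A,B) = Σ [S(a→b) + S(b→a)] / Σ [S(a→a) + S(b→b)]`

  over the RBH pairs of genomes A and B, with `1 − GSS` fed to neighbor
  joining; and

* a **functional-content** view: per-genome sets of annotated functions,
  compared with Jaccard distances `Jd(A,B) = 1 − |A∩B|/|A∪B|`, clustered
  hierarchically (Ward), with cluster–environment association tested by the
  hypergeometric tail `P(X ≥ k)` under Benjamini–Hochberg FDR control, and
  group-specific ("adaptive") functions detected with an exact presence test
  gated at ≥ 80% in-group presence.

Congruence between the two views is quantified with Robinson–Foulds
symmetric differences. The package is aimed at comparative genomicists who
have pairwise hit tables, domain-assignment tables and isolation-environment
labels, and want the whole chain — filters, scores, clustering, enrichment,
congruence — reproducible and testable. A built-in simulator evolves genomes
on a phylogeny with environment-specific gene pools, so every stage can be
validated against planted truth without downloading anything.

## Worked example

Simulate a 30-genome study with three partly polyphyletic environments and
planted environment pools, then run the full pipeline:

```r
library(convergene)
cfg <- pipeline_config(simulate = simulation_config(n_genomes = 30, seed = 1),
                       seed = 1)
report <- run_pipeline(cfg, "demo_run")

round(report$agglomerative_coefficients, 3)
#>     ward  average complete   single
#>    0.924    0.769    0.792    0.721
```

Ward gives the cleanest dendrogram (agglomerative coefficient 0.924), so it
is carried forward. The k = 3 cut of the content dendrogram recovers the
environments exactly and every environment is significantly associated with
its cluster:

```r
report$associations[report$associations$significant & report$associations$k == 3,
                    c("k", "cluster", "environment", "k_in", "n_cluster", "q")]
#>  k cluster environment k_in n_cluster            q
#>  3       3     Aquatic   10        10 1.497753e-07
#>  3       2 Facultative    7         7 1.473622e-06
#>  3       1 Terrestrial   13        13 7.515039e-08
```

`q` is the BH-adjusted hypergeometric p-value: e.g. all 10 Aquatic genomes
land in one cluster of 10, which would essentially never happen under random
assignment. Meanwhile the phylogenetic and content views disagree exactly
where they should:

```r
report$congruence$rf
#>              gss_nj reference content_ward
#> gss_nj            0         0           48
#> reference         0         0           48
#> content_ward     48        48            0
```

The GSS neighbor-joining tree is identical to the true (reference) tree
(RF = 0), while the content dendrogram differs from both by 48 bipartitions
— the planted convergent gene pools have pulled polyphyletic same-environment
genomes together. The 81 reported adaptive functions (`report$adaptive`)
recover the planted pool families with their direction of enrichment.

All stage artifacts (GSS matrix, trees, ortholog groups with occupancies,
profiles, Jaccard distances, merge tables, association and adaptive-function
tables, run log) are written to the output directory as TSV/Newick.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/convergene.R", package="convergene"))')" \
  run --out demo_run --seed 1
```

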