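Package: convergene
Title: Detecting Environmentally Driven Gene-Content Convergence on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics pipeline for testing whether bacterial genomes
    isolated from similar environments share gene content beyond what their
    phylogeny explains. Builds reciprocal-best-hit (RBH) orthology from BLAST-style
    hit tables with alignment-coverage filtering, selects core and Core-70 ortholog
    sets, computes Genomic Similarity Score (GSS) matrices and neighbor-joining
    trees, derives per-genome functional profiles from filtered domain assignments,
    clusters Jaccard distances hierarchically (with agglomerative coefficients and
    silhouettes), tests cluster-environment association with hypergeometric
    enrichment under FDR control across dendrogram cuts, detects putatively
    adaptive gene families, and measures tree congruence with Robinson-Foulds
    symmetric differences. Includes a gene-content simulator that evolves genomes
    on a phylogeny with environment-specific convergent gene gain, providing
    planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    cluster,
    data.table,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
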