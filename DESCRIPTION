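Package: pinepop
Title: Haploid-Aware Population Genomics for Conifer Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Analysis", "Toolkit", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genomic inference from mixed haploid
    (megagametophyte) and diploid sequencing panels in conifers. Implements
    paralog-aware variant quality control using haploid heterozygote
    screening, heterozygosity excess, read-ratio deviation and
    multi-population Hardy-Weinberg tests aggregated in 250 bp error
    windows; nucleotide diversity by site degeneracy class, Tajima's D and
    folded site-frequency-spectrum projection with Stairway-plot export;
    Weir-Cockerham F_st, AMOVA, PCA and PC-space shared-ancestry profiles;
    isolation-by-distance regression with Rousset's Nm and Ennos
    pollen/seed gene-flow ratios from nuclear, mitochondrial and
    chloroplast markers; the proportion-of-shared-rare-alleles (PSRA)
    statistic; organelle haplotype networks with Louvain communities; and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
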