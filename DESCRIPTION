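Package: domestiscan
Title: Selection Scans, Introgression Tests and Convergence Analyses for
    Domestication Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based selective-sweep scanning of wild versus domestic
    cohorts with five statistics (pooled heterozygosity, Tajima's D, Fay and
    Wu's H, iHS, and a composite-likelihood-ratio sweep model), per-method
    significance thresholds including a shuffle-based null for pooled
    heterozygosity, a two-or-more-method consensus sweep caller with a
    multi-rule gene filter, a four-population introgression test with block
    jackknife standard errors, outgroup allele polarization, count-based
    dN/dS, deleterious-variant burden tests, genomic-region and gene-set
    enrichment, a network hub-degree resampling test, and a forward
    Wright-Fisher simulator that generates fully self-contained synthetic
    cohorts (genotypes, outgroup, annotations, networks, gene sets, site
    scores) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    seqinr,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
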