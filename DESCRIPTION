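Package: aflprad
Title: Comparative Phylogeographic Analysis of AFLP and RADseq Markers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare dominant AFLP presence/absence fingerprints
    with RADseq SNP genotype matrices in a phylogeographic setting:
    replicate-guided AFLP locus denoising, ordination-based outlier
    screening, Jaccard and Gower dissimilarities, ANOSIM and Mantel
    permutation statistics, non-metric multidimensional scaling, a
    locus-rarefaction engine that measures how many SNP loci reproduce the
    full dataset's regional signal, and a paired synthetic-data generator
    with known regional structure so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    MASS
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
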