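Package: bulkmap
Title: Bulked-Segregant Analysis Mapping of a Dominant Locus from Pooled
    Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of next-generation-sequencing aided
    bulked-segregant analysis (BSA-seq) for a dominant monogenic trait in an
    F2 population. Simulates F2 meiosis under the Haldane (no-interference)
    model, phenotype-selected bulks, and pooled allele counts with sequencing
    error; computes per-site SNP-index, delta-SNP-index and Euclidean-distance
    statistics; smooths them along the genome and calls candidate regions
    against the theoretical F2 threshold; narrows the interval by
    recombinant counting in the recessive class; and provides Mendelian
    segregation chi-square testing and spectrophotometric chlorophyll and
    carotenoid quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
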