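Package: bingogs
Title: Gene-Ontology-Guided Marker Subset Selection for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Selects compact, informative SNP marker panels for genomic
    prediction by combining Gene Ontology biological priors with a bin-based
    combinatorial optimization over GWAS p-value strata. Provides genotype,
    phenotype, gene-model and GO-annotation readers, marker quality control
    (minor allele frequency, Hardy-Weinberg, windowed LD pruning), a GBLUP
    prediction core with spectral REML variance-component estimation, an
    EMMAX-style mixed-model association scan, Monte Carlo estimation of the
    marker-budget upper limit with moving-average plateau detection, a
    chain-wise rolling combination optimizer over p-value bins, an evaluation
    harness with replicated train/test splits and paired one-tailed t-tests,
    and a seed-deterministic synthetic-data generator with LD-blocked
    genotypes, GO-annotated gene intervals and planted quantitative trait
    nucleotides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
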