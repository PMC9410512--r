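Package: gfabric
Title: Genomic Fabric Characterization of Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes a transcriptome per condition by three independent
    feature families: average expression level relative to the median gene
    (AVE), relative expression variability across biological replicates
    estimated as the mid-interval of the chi-square confidence interval of
    the coefficient of variation (REV), and all-pairs Pearson correlation of
    log2 expression (COR). From these it derives relative expression control
    scores for genes (REC) and pathways (PREC), a gene commanding-height
    hierarchy (GCH) identifying the gene master regulator (GMR), per-gene
    regulation calls with noise-adaptive fold-change cut-offs, weighted
    individual regulation (WIR) and individual transcriptomic distance (ITD),
    pathway-level aggregates (WPR, PTD), coordination-network classification
    of gene pairs (synergistic, antagonistic, independent), and treatment
    recovery metrics (GER, PRE, CPR) for reference/disease/treated designs.
    Includes a synthetic-data generator with known ground truth and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    fgsea,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
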