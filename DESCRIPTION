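Package: introgmap
Title: Transcriptome-Based Genotyping and Salt-Tolerance Analysis of Rice
    Introgression Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing introgression lines produced by
    marker-assisted backcross (MABC) breeding, centred on transcriptome-based
    genotyping: per-transcript variant-excess classification of donor versus
    recurrent-parent origin, delimitation of introgression blocks along
    chromosomes, and gene inventories per block. Also provides a simulator of
    the full study design with known ground truth (donor-segment mosaics,
    variant-count profiles, negative-binomial expression counts, salt-stress
    phenotypes), MABC simulation with foreground/background selection and
    recurrent-parent genome (RPG) recovery accounting, salt-tolerance
    phenotype indices (relative traits, electrolyte leakage, Na+/K+ molar
    ratios, SES score distributions), and differential-expression calling
    with a cross-genotype salt-response overlap statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
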