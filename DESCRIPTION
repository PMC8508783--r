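Package: climescan
Title: Joint Selection-Signature and Differential-Methylation Scanning for
    Two-Group Climate Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to contrast two environmental groups of individuals at the
    genetic and the epigenetic level. Implements a per-SNP Weir-Cockerham FST
    selection scan with candidate-region construction by merge-and-pad, and a
    MeDIP-seq differential-methylation pipeline over 100-bp genome windows:
    TMM normalization, quantile-adjusted conditional negative-binomial exact
    testing with a robust common dispersion, Storey q-values, mean/variance
    changepoint delineation of methylation peaks, Wilcoxon group testing of
    peaks, and a WGS-coverage confound filter for copy-number artefacts. A
    synthetic-data generator produces genotype and methylome datasets with
    planted signals and ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
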