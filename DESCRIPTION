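Package: footmix
Title: Multi-State Mixture Modelling of DNase-Seq Cut Profiles for
    Transcription Factor Binding Site Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcription factor binding sites from strand-specific
    DNase I cut profiles around candidate motif instances. A mixture model with
    an unbound state, a monomer binding mode and optional cooperative dimer
    binding modes combines a multinomial-logistic prior on sequence-derived
    features with a chromatin likelihood factorized into a negative binomial
    component for the total cut count and a binned multinomial component for
    the spatial cut distribution. Parameters are fitted by
    Expectation-Maximization with a shrinkage estimator for the spatial
    profiles and quasi-Newton maximization steps. Includes ChIP-seq-based
    evaluation (precision-recall, ROC, Spearman correlation with peak height),
    a Binding-in-Closed-Chromatin statistic for quantifying pioneer-factor-like
    activity, a generative simulator for testing, and readers for BED,
    narrowPeak, bedGraph and BAM inputs.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    nnet,
    pROC,
    optparse
Config/testthat/edition: 3
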