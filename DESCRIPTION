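Package: enhact
Title: Variational Inference of Promoter and Enhancer Activities for
    Enhancer-Gene Interaction Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates latent promoter and enhancer activities from
    gene-level RNA-seq counts, chromatin-accessibility counts over
    candidate regulatory elements, and chromatin contact frequencies,
    using a gamma-Poisson model of transcriptional bursting fitted by
    mean-field variational Bayes with generalized inverse Gaussian
    posteriors for chromatin openness.  Each enhancer-gene pair within a
    distance window is scored by its relative contribution to the
    target gene's transcription (activity-by-contact, normalized per
    gene).  Includes preprocessing of accessibility peaks and binned
    contact maps, a power-law distance fallback for contacts, a
    generative simulator with known ground truth, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
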