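Package: grud
Title: Reference-Free Genotype Imputation with an Adversarially Trained
    Bidirectional GRU
Version: 0.1.0
Authors@R:
    person("GRUD", "Maintainers", email = "grud@example.org", role = c("aut", "cre"))
Description: Trains a generative model for genotype imputation from a phased
    haplotype reference panel: observed variants are one-hot encoded, passed
    through a sequential feature layer (linear, leaky ReLU, batch
    normalisation) and a stack of bidirectional gated recurrent units with
    residual skip-connections, and per-target softmax heads emit allele
    probabilities for unobserved variants. A small discriminator network is
    trained jointly in a GAN-style loop to tell generated haplotype slices
    from real reference haplotypes. Includes minor-allele-frequency-weighted
    cross-entropy loss variants, a founder-mosaic haplotype simulator with
    controllable linkage disequilibrium, dosage R-squared evaluation
    (overall, average-per-variant and MAF-binned), and VCF input/output.
    Once trained, a checkpoint imputes new samples without access to the
    reference panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    Rsamtools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
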