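Package: scgeno
Title: Quality Control and Confidence Rescoring for Single-Cell SNP Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quality control and noise reduction of single-cell
    SNP-array genotype calls. Reads Illumina genotype-call (GTC) batches
    together with their manifest, genotype-cluster and sample-sheet metadata,
    applies the six-parameter affine intensity normalization, computes MA
    log-intensity features, and rescores every genotype call with a two-layer
    model: a trainable random-forest first layer seeding per-individual
    Gaussian discriminant analysis, whose posterior probability that a call is
    correct becomes the call's quality score. Includes call-rate and
    heterozygosity summaries, genotype PCA for kinship and aneuploidy checks,
    score-threshold sweeps, and a synthetic whole-genome-amplification noise
    simulator (allele drop-out and drop-in) so the full pipeline can be
    exercised and benchmarked offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    optparse,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    jsonlite
Config/testthat/edition: 3
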