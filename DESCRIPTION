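Package: dhpanel
Title: Molecular Characterization of Doubled-Haploid Panels from Recurrent
    Selection Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize panels of doubled-haploid (DH) maize lines
    derived from different cycles of recurrent selection, together with a
    forward-in-time simulator of the breeding scheme that produced them.
    Implements marker and line quality control, minor-allele-frequency and
    unbiased expected-heterozygosity summaries, Euclidean genetic distances
    with UPGMA dendrograms, per-locus and multi-locus Weir-Cockerham F_ST,
    centered-IBS kinship and principal component analysis with BIC model-size
    selection, Hill-Weir linkage-disequilibrium decay fitting, and a two-state
    hidden Markov model for identity-by-descent segment detection used to
    quantify founder genetic contributions. A configuration-driven pipeline
    orchestrates all stages and writes a reproducible report bundle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    ape,
    jsonlite,
    minpack.lm,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
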