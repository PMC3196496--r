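Package: genebirth
Title: Gene Age, Developmental Expression Bias, and Selection on New Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline linking gene origination age to developmental-stage-
    and brain-region-biased expression. Assigns origination branches from
    ortholog presence/absence on a rooted species tree (Dollo parsimony),
    calls expression presence from EST library counts with bootstrap and
    subsampling controls, quantifies RNA-seq expression with
    mappability-corrected RPMK (unique 32-mer effective lengths) and a
    binomial likelihood-ratio test for two-group differential expression,
    crosses age classes with expression bias (Fisher tests, branch-wise
    binomial profiles, genomic cluster pooling, feature proximity, term
    enrichment), and layers McDonald-Kreitman statistics with a
    Poisson-random-field selection-intensity estimator and Nei-Gojobori
    Ka/Ks. A synthetic-data module generates every input with known truth
    so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
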