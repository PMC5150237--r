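Package: mhcmate
Title: MHC-Dependent Mate Choice Analysis with Candidate-Pool Randomization
    and Mixed-Model Inference
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing major histocompatibility complex (MHC) dependent
    female mate choice from pedigree and candidate-male observation data, as used
    in studies of polygynous mammals with unresolved multi-locus MHC genotypes.
    Implements five MHC dissimilarity and diversity indices computed on pooled
    allele sets, a Monte Carlo randomization test that reassembles couples within
    each female's observed candidate pool, binomial mixed-model (GLMM) inference
    with four crossed random intercepts and parametric-bootstrap likelihood-ratio
    tests (including interaction tests with chemosensory receptor genotypes), a
    permutation-based exact test of linkage disequilibrium for arbitrary
    contingency tables, an entropy-based (oligotype) amplicon allele-calling
    workflow with reference-free chimera filtering, translated-homology filtering
    and Mendelian trio validation, and a synthetic population generator with a
    tunable mate-preference mechanism for power and calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
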