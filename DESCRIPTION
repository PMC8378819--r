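Package: reefcross
Title: Quantitative Genetics of Selective Breeding for Coral Heat Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for selective-breeding experiments that cross
    heat-experienced and heat-naive coral populations and score larval heat
    survival together with pooled 2b-RAD-style sequencing. Provides a
    forward simulator of diverged source populations, half-sib/full-sib
    cross designs, genotype-dependent thermal mortality and pooled
    read-count sampling; threshold-based parental genotype and pooled
    minor-allele-frequency calling; survival statistics including
    origin/family models with partial eta-squared, survival indices and
    Gibbs-sampled variance-component heritability; per-SNP
    allele-frequency-survival association and beneficial-allele scoring of
    parents; heat-selection scans with PCA of hybrid allele-frequency
    shifts; and Fisher-test Gene Ontology enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    car,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
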