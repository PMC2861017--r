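Package: hapblup
Title: Haplotype Copy-Number Prediction for Ungenotyped Animals and
    Marker-Assisted BLUP
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the number of copies of marker haplotypes (nhc) carried
    by ungenotyped animals from pedigree information and genotyped relatives,
    by treating the copy count of each haplotype class as a near-fully
    heritable trait in Henderson's mixed model equations, and uses the
    predictions as random-regression covariates in marker-assisted breeding
    value estimation (MABLUP).  Ships pedigree utilities (Meuwissen-Luo
    inbreeding, sparse inverse additive relationship matrix), a Monte Carlo
    simulator of a nested full-sib half-sib livestock breeding scheme with
    drift-generated linkage disequilibrium and BLUP truncation selection,
    multi-allelic linkage-disequilibrium statistics, gene-assisted and
    conventional BLUP baselines, and a replicate evaluation harness for
    accuracy, regression-slope and bias statistics of estimated breeding
    values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
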