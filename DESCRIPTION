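Package: episcreen
Title: Prototype-Based Screening for SNP-SNP Compositional Epistasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screening of SNP pairs in case-control data for compositional
    epistatic effects described by two-locus, two-allele, two-phenotype,
    complete-penetrance (TTTC) disease models. Instead of letting the data
    pick a best-fitting disease model for every pair (as the MDR and
    ratio-split baselines do), a small set of prototype models is selected a
    priori by clustering all non-trivial TTTC models under a
    phi-coefficient-based directional distance, calibrated by prevalence,
    heritability and minor-allele frequencies under Hardy-Weinberg
    equilibrium. Includes the chi-square pair-screening engine with marginal
    and sequential procedures, MDR and ratio-split baselines, a case-control
    simulation harness (penetrance- and odds-parameterized models,
    pathological two-pair scenarios, null data) and F-measure and
    null-inflation evaluation drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
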