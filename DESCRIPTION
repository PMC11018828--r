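Package: cispen
Title: Testing cis-Regulatory Modification of Rare-Variant Penetrance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether common cis-eQTL-predicted gene
    expression modifies risk of neurodevelopmental disorders and the
    penetrance of rare, inherited, putatively damaging coding variants.
    Implements weight-based prediction of genetically-determined gene
    expression from dosages or phased haplotypes, genotype-array and trio
    quality control (including an exact Hardy-Weinberg test and Mendelian
    error counting), classification of rare inherited variants into
    penetrance-relevant categories, a per-gene TWAS logistic scan with an
    outlier-expression enrichment test, within-family paired and
    percentile-rank case/control penetrance tests with noncentral-t power
    calculations, and a synthetic-data generator in which the expression of
    the wild-type haplotype modifies penetrance under case/trio
    ascertainment, with known ground truth for parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
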