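Package: rarecollapse
Title: Gene-Based Rare-Variant Collapsing Analysis for Case-Control Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-based collapsing analysis of rare variants in
    case-control exome sequencing studies. Implements case/control coverage
    harmonization, qualifying-variant models combining internal leave-one-out
    and external reference allele-frequency filters with functional and
    deleteriousness gates, per-gene carrier collapsing with two-sided Fisher
    exact tests and odds ratios, Bonferroni multiplicity thresholds,
    permutation-based QQ expectation and genomic inflation lambda,
    genotype-based ancestry clustering with within-cluster reruns, gene-set
    testing, and diagnostic phenotype scoring. A synthetic-cohort simulator
    with multiplex sibling-pair families, population structure and risk-gene
    spiking supports end-to-end testing without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
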