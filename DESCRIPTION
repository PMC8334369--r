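Package: placentamir
Title: Placental miRNome Expression Dynamics, Correlation Landscape and
    miR-eQTL Mapping
Version: 0.1.0
Authors@R:
    person("Placentamir", "Developers", email = "placentamir@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for bulk placental miRNA-seq analysis
    across gestation: median-count filtering and median-of-ratios
    normalization, negative-binomial Wald differential expression between
    trimesters and clinical groups (with optional fetal-sex adjustment), a
    nine-pattern taxonomy of gestational expression dynamics, a genome-wide
    miRNA-mRNA Spearman correlation landscape with hierarchical miRNA
    grouping, thresholded correlated-gene lists and hypergeometric
    enrichment against a custom background, and a windowed cis miR-eQTL
    scan with MAF/HWE filtering, pregnancy-trait association and
    fixed-effect meta-analysis. Includes a negative-binomial cohort
    simulator with planted effects and ground truth for end-to-end
    validation without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
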