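Package: nitrophase
Title: Turbidostat Nitrogen-Starvation Time-Course Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multi-omics time courses of a
    phytoplankton culture switched from nitrogen-replete to
    nitrogen-starved feed in a turbidostat. Estimates division rates from
    daily overflow volumes, converts macromolecule quotas into stored
    combustion-energy equivalents, quantifies chlorophylls and carotenoids
    from acetone-extract absorbances, segments the time course into
    replete/transition/starved phases by principal component analysis of
    physiological traits, filters differentially expressed transcripts and
    responsive metabolites, and screens every compound-gene pair for
    unit-slope co-variation of their log2 fold-change patterns. A
    Droop-quota turbidostat simulator generates complete synthetic
    experiments with planted ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
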