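Package: phenodgi
Title: Yeast Phenomic Drug-Gene Interaction Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of drug-gene interaction from yeast
    knockout/knockdown phenomic screens of nucleoside analog cytotoxicity.
    Fits logistic growth curves to plate-culture intensity time series to
    obtain cell proliferation parameters (carrying capacity K, maximum
    specific growth rate r, and time to half carrying capacity L), scores
    dose-dependent drug-gene interaction as shift-corrected linear-regression
    z-scores against replicate reference cultures, clusters interaction
    profiles by recursive expectation-maximization Gaussian mixture
    clustering (REMc), summarizes gene function by hypergeometric GO-term
    enrichment and GO-term averaging (GTA), and integrates yeast interaction
    classes with cancer cell-line expression/sensitivity data through
    yeast-human homology to call underexpression-sensitivity (UES) and
    overexpression-sensitivity (OES) candidates. Includes a synthetic-data
    generator emulating 384-culture array experiments with planted
    interaction effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
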