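Package: oilcomm
Title: Ensemble Co-Occurrence Networks and Keystone Scoring for
    Crude-Oil-Degrading Bacterial Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed microbial association networks from compositional
    genus-abundance tables using an ensemble of five similarity and regression
    measures (Bray-Curtis, Pearson, Spearman, mutual information, and a
    componentwise L2-boosted linear model), with a renormalization ("ReBoot")
    permutation null that respects the compositional closure of relative
    abundances, Brown's method for merging dependent per-measure p-values, and
    Benjamini-Hochberg error control. Ranks keystone taxa by a homogenized
    centrality key-score (degree + closeness - betweenness) and links taxon
    abundances to crude-oil degradation efficiency (TPH and SARA fractions)
    through a combined permutation-standardized coefficient. Includes a
    compositional community simulator with planted associations and
    keystone-linked degradation responses for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    jsonlite,
    xml2,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
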