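Package: gopredict
Title: Predictive Value of Transcript Expression for Protein Abundance
    Within Gene Ontology Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well transcript expression predicts protein
    expression within Gene Ontology categories in paired
    transcriptomic/proteomic data, as in adult primate brain studies.
    Fits per-category ordinary least squares regressions of protein on
    transcript log-expression, builds a size-matched permutation null for
    categorical R-squared, screens covariates (category size, molecular
    abundance, gene length, synthesis and degradation rates), fits a
    stability multiple regression, and scores rank-order concordance of
    category predictivity across species and brain regions. Includes a
    synthetic paired-expression generator with analytically known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
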