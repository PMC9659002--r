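Package: fimrisk
Title: Fuzzy Inference and Random Forest Weighting of Mortality Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighting and ranking of country-level mortality risk factors by
    fuzzy comprehensive evaluation. Crude mortality rates are classified into
    five quintile risk levels; three weight groups are derived by chi-square
    contingency analysis, RIDIT (mid-rank) analysis and the Analytic Hierarchy
    Process; each weight group is composed with a fuzzy membership matrix and
    the group closest to the reference membership vector, by the lattice
    degree of nearness, is selected. A random-forest stage classifies the
    outcome risk level from the factor levels and ranks factors by impurity
    importance for comparison. Includes a synthetic generator of Global
    Burden of Disease style long-format mortality tables with planted
    factor-outcome associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
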