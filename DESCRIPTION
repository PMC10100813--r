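Package: paleoleaf
Title: Integrated Trait and Insect-Herbivory Analysis of Fossil Leaf Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the integrated analysis of dicot leaf assemblages from
    fossil sites: a nested dataset cascade from scored specimens to a cleaned
    modelling set; trait-combination-type (TCT) classification from four binary
    architectural characters; quantitative leaf traits including leaf mass per
    area (LMA) estimated from petiole-width allometry and phenology classes
    inferred from LMA thresholds; insect damage-type metrics (damage frequency,
    occurrence, observed and analytically rarefied richness with standard
    deviations, herbivory index) with functional-feeding-group scopes;
    chained-equation Bayesian-regression imputation of missing LMA; and the
    downstream multivariate stage (standardised trait PCA with variable
    contributions, Gamma and binomial GLMs with AIC stepwise selection, type-II
    likelihood-ratio ANOVA and pseudo R-squared). A synthetic two-site
    assemblage generator with a full truth record makes every stage testable
    without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
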