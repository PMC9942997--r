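Package: woodear
Title: Substrate Formulation Modelling for Wood Ear Mushroom Cultivation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models cultivation outcomes of the wood ear mushroom
    (Auricularia cornea) as functions of substrate composition (beech
    sawdust, hornbeam sawdust, wheat bran and rice bran percentages).
    Ships a 16-substrate cultivation trial summary (means and standard
    errors over 12 replicate bags), a seeded synthetic replicate
    generator matching that summary structure, Box-Cox normalisation,
    PCA-based outlier screening, five-fold cross-validation with ten
    replicates, a single-hidden-layer perceptron regressor (tansig
    hidden layer, linear output) trained by backpropagation whose
    hidden-layer size is selected by an elitist genetic algorithm,
    leave-one-input-out variable sensitivity (VSE/VSR) analysis, and a
    bidirectional stepwise linear regression baseline evaluated under
    identical cross-validation plans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
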