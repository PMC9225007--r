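Package: micos
Title: Modeling, Interpretation and Design of Synthetic Microbial Community Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and designing the dynamics of synthetic
    microbial communities and their fermentation end products. Provides a
    generalized Lotka-Volterra (gLV) simulator with optional third-order
    interactions, periodic dilution (passaging) and observation noise; an
    LSTM recurrent model of species abundance and metabolite trajectories
    trained with randomized teacher forcing, including an endpoint
    feed-forward metabolite head and a joint species-plus-metabolite
    variant; model interpretation via local surrogate (LIME-style)
    explanations, backpropagated gradient sensitivities and
    prediction-sensitivity statistics; model-guided community design by
    exhaustive enumeration, k-means representative selection and two-level
    extreme-tail ("corner") selection; and minimum-spanning-tree divisive
    clustering of metabolite trajectories with decision-tree rule
    extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    rpart,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
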