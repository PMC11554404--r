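Package: feralcoats
Title: Coat-Morph Analysis of Feral Cat Camera-Trap Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing coat colour and pattern morphs of feral cats
    (Felis catus) recorded by camera-trap networks. Maps raw pelage labels
    (pattern, colour, white markings) onto five modelling categories, groups
    images into independent detection events, applies a minimum-operation
    retention rule for true absences, derives per-site modal coat types, and
    estimates the number of unmarked melanistic individuals from an
    images-per-cat ratio. Fits multinomial logistic regression by
    Newton-Raphson maximum likelihood, with Wald odds-ratio intervals, for a
    spatial model (modal coat type versus site covariates) and a temporal
    model (nightly coat-type captures versus moon luminosity and weather).
    Computes the proportion-of-dates-with-events (PDE) activity index with
    site-level bootstrap standard errors, classifies nights by lunar
    illuminated fraction, and simulates complete synthetic surveys with known
    ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    nnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
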