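Package: kermagmdh
Title: Air Kerma Prediction in an X-ray Tube Radiation Field with GMDH
    Polynomial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts air kerma at any position (tangent angle, polar angle,
    source distance) and tube voltage inside the conical radiation field of a
    diagnostic X-ray tube using a Group Method of Data Handling (GMDH)
    self-organizing polynomial network built from quadratic two-input
    least-squares neurons with external-criterion layer selection. Includes
    an analytic surrogate of the Monte-Carlo-computed kerma field (anode heel
    effect, inverse-square distance law, voltage power law, seeded tally-like
    noise) anchored to a packaged reference table, mean-relative-error and
    root-mean-square-error evaluation with a seeded 70/30 train/test
    protocol, and a command-line interface wiring generation, training,
    prediction and evaluation together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
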