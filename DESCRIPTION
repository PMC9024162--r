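Package: isletscreen
Title: Reaction-Diffusion Screening of Hydrogel-Encapsulated Islets of
    Langerhans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic screening of oxygen, glucose and insulin transport
    in a spherical islet of Langerhans surrounded by a cell-free hydrogel
    shell. A finite-volume radial solver integrates coupled
    diffusion-consumption-secretion equations to steady state; local oxygen
    partial pressure is compared against a critical survival threshold to
    predict the viable islet volume fraction, and glucose-driven insulin
    secretion is reduced to a normalized secretion percentage. A sweep
    engine evaluates scenario grids over inflow oxygen, bath glucose, islet
    diameter and shell thickness, producing screening tables for
    bioartificial-pancreas capsule design. Analytic zeroth-order oracles and
    seeded scenario generators make every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    deSolve,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
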