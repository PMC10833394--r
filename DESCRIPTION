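Package: diffsep
Title: Simulation and Separation of Diffuse Scattering from Binary Substitutional Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-crystal diffuse scattering arising from binary
    substitutional disorder with one disordered site per unit cell. Simulates
    the molecular form-factor component (squared difference of molecular form
    factors) and the chemical short-range-order component (Warren-Cowley cosine
    series) on reciprocal-space plane grids, generates disordered occupancy
    configurations by Monte Carlo annealing, assembles normalized paired
    training datasets with synthetic detector artefacts, trains a pair of
    parallel conditional image-translation networks (U-Net generators with
    patch discriminators, implemented natively) to separate the two components,
    and refines Warren-Cowley parameters and structural models from the
    separated components by linear least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
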