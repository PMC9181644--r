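Package: ionrbe
Title: Mechanistic Monte Carlo Modelling of Cell Survival, DNA Repair
    Kinetics and Dose-Rate-Dependent RBE for Photon and Ion Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of cell survival after photon and ion
    irradiation based on the clustering of DNA double-strand breaks (DSB)
    within ~2 Mbp chromatin ("giant-loop") domains, extended with repair
    kinetics of isolated and clustered DSB to model dose-rate effects.
    Includes an amorphous track-structure model (Kiefer-Chatterjee radial
    dose with radical diffusion and a three-step parametrization), exact
    per-domain expectation engines for sparsely ionizing radiation,
    iso-effect (TD50) solvers, three definitions of relative biological
    effectiveness (fixed-reference, dose-rate adapted, no-repair), the
    TD50-ratio dose-rate correction factor for spread-out Bragg peak RBE
    approximation, and least-squares fitting of the per-damage lethality
    parameters to TD50-versus-fractionation data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
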