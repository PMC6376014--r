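Package: recoilrange
Title: Secondary-Neutron Range Verification for Proton Therapy with a
    Proton-Recoil Telescope
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for range verification in
    proton therapy based on secondary neutrons. Provides a fast synthetic
    Monte-Carlo generator of secondary-neutron production in a water phantom
    irradiated by a proton pencil beam, with conversion of neutrons to recoil
    protons in a hydrogen-rich converter and detection in two ideal tracking
    planes; an iterative Monte-Carlo acceptance/rejection back-projection
    algorithm that estimates neutron production locations on an image plane
    and a range landmark (beta, the mean plus one standard deviation of the
    reconstructed production depths); and analysis utilities for repetition
    and bunching uncertainty estimation, histogram root-mean-square-error
    evaluation, and the linear correlation between the landmark and the
    primary beam range.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
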