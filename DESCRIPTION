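Package: connforge
Title: Matched Structural and Functional Connectomes with QC Phenotypes
Version: 0.1.0
Authors@R: person("connforge", "developers", role = c("aut", "cre"),
    email = "connforge@example.org")
Description: Builds the bespoke computational stages of a parcellation-driven
    neuroimaging pipeline: refinement of tissue masks and construction of the
    labeled gray-matter/white-matter interface used to seed tractography;
    parcellated BOLD time-series extraction and Pearson functional
    connectivity; assembly of structural connectivity weights and tract-length
    matrices from probabilistic-tractography streamline counts, exported in
    TheVirtualBrain connectivity zip format; image-derived phenotypes (tSNR,
    framewise displacement, connectivity summary statistics) with
    threshold-based pass/fail evaluation and a standalone HTML QC report; and
    a mean-centered partial least squares analysis with permutation and
    bootstrap-ratio inference that validates phenotypes against ordinal QC
    ratings. Ships synthetic phantom generators with analytically known ground
    truth so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    base64enc,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
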