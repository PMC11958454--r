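Package: aggretrack
Title: Single-Molecule Quantification of Protein Aggregates in Live Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for fluorescence microscopy of
    protein aggregates in budding yeast. Generates synthetic Slimfield and
    confocal acquisitions with known ground truth (Brownian aggregate motion,
    per-fluorophore stochastic photobleaching, Poisson/Gaussian camera noise);
    detects fluorescent foci inside per-cell regions of interest; localizes
    foci to sub-pixel precision by iterative Gaussian fitting and links them
    into tracks; estimates molecular stoichiometry by normalising initial
    track intensity against a single-molecule brightness calibrated from
    stepwise photobleaching; estimates diffusion coefficients from the
    initial gradient of the mean squared displacement; and computes
    population statistics (aggregate-positive fractions, mother/daughter
    asymmetry, organelle colocalization, inheritance scoring, condition
    comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
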