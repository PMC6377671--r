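Package: meminsert
Title: Membrane Insertion Kinetics, Orientation and Localisation of Small
    Molecules in Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory- and structure-level analyses of the early stages of
    small-molecule insertion into phospholipid bilayers. Estimates insertion
    association constants from mean first passage times (K_in = A*Lz/<W>),
    classifies molecular orientation against the bilayer normal into
    horizontal/perpendicular preferences, builds lipid-component contact
    histograms with an early-window control, and computes molecular rigidity
    (significant low-frequency IR mode counts), point-charge dipole moments
    and intramolecular hydrogen-bond distances. Ships a synthetic drift-
    diffusion trajectory generator emulating a 128-lipid POPC/DMPC bilayer
    setup so every analysis stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
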