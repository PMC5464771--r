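Package: cellmech
Title: Quantitative Analytics for Cell Mechanosensing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the quantitative stages of
    substrate-stiffness mechanosensing experiments on lymphocytes and
    antigen-presenting cells. Computes per-track migration statistics and
    arrest (stop-signal) classification from 2D cell trajectories, fits the
    Hertz spherical-contact model to cantilever force-indentation curves to
    recover cell Young's moduli, converts parallel-plate shear rheometer gap
    sweeps of polyacrylamide hydrogels to Young's moduli, and evaluates a
    theoretical ligand surface-density model for biotin-streptavidin
    functionalized gels. A synthetic-data module generates trajectories,
    force curves and gap sweeps with known ground truth so that every
    pipeline stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
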