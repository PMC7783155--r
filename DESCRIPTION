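Package: spheroidCA
Title: Cellular-Automaton Simulation and Trajectory Quantification of
    Spheroid Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lattice cellular-automaton model of collective cell migration
    out of tumour spheroids. Per-cell movement probabilities compose four
    mechanisms: Brownian random movement (a Gaussian kernel), self-generated
    chemotaxis (an explicit finite-difference reaction-diffusion field with
    receptor saturation), mechanical cell-cell interaction (an occupancy
    convolution), and proliferation, under strict volume exclusion. The
    package also implements the matching single-cell trajectory statistics:
    mean relative radial migration (RRM), per-track diffusion-coefficient
    estimation, invasion velocity from the early linear regime, size
    stratification and Kolmogorov-Smirnov comparison, with TrackMate-style
    spots CSV import/export, a synthetic Brownian track generator and a
    command-line interface for reproducible cohort runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
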