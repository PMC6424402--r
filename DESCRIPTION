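Package: flagrelics
Title: Spatial, Population and Density-Map Analysis of Polar Flagellar
    Ejection and Motor Relics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative tools for studying the ejection of polar flagella
    by gamma-proteobacteria under nutrient depletion and the motor "relic"
    structures left in the outer membrane. Implements Clark-Evans
    nearest-neighbour analysis of motor and relic placement on cell poles
    with the ellipse pole-area convention and constrained Monte-Carlo null
    cohorts; population flagellation accounting (t-based confidence
    intervals, absolute flagella from CFU, pole occupancy classes);
    hook-end breakage statistics for shed filaments; swim-track
    velocimetry; periplasmic distance morphometrics; and density-map
    operations on cryo-ET subtomogram averages (MRC2014 input/output,
    n-fold rotational symmetrization, symmetry-order detection, Fourier
    shell correlation with threshold resolution, masked composite merging,
    ring morphometry). A synthetic-data module generates every input class
    with known ground truth, including hard-core, grid and clustered point
    patterns and cylindrically symmetric motor/relic phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
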