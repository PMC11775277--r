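Package: ethome
Title: Larval Behavior Classification, Ethogram Statistics and Circuit
    Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying Drosophila larva defensive behavior from
    tracked midline ("spine") time series: kinematic posture features (spine
    order parameter, movement shape factor, length-normalized velocities and
    their spine projections), a two-layer random-forest refinement of coarse
    Bend/Hunch classifications into Head Cast, Static Bend, Hunch,
    Head-and-Tail and C-shape actions, population statistics (ethograms,
    cumulative action probabilities, transition matrices, chi-square tests
    with Benjamini-Hochberg correction, Kolmogorov-Smirnov velocity
    comparisons), fraction-of-input summaries of synapse tables from
    electron-microscopy reconstructions, and dF/F0 processing of calcium
    imaging traces.  A synthetic-trajectory generator with known ground
    truth supports end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
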