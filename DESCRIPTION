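Package: allokin
Title: Allosteric Trajectory Analysis for Kinase Receptors: Wavelet Events,
    Frame-Set PCA, Current-Flow Networks and WHAM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for studying allosteric
    regulation in type 1 serine/threonine kinase receptors (STKR1) and
    similar systems: salt-bridge state metrics from coordinate
    trajectories; Morlet-wavelet event detection with chi-squared
    denoising, density clustering and silhouette-scored temporal
    partitioning into frame sets; frame-set-restricted principal component
    analysis with amplitude-scaled mode vectors and a residue-to-helix
    separation metric; current-flow betweenness scoring of residue
    correlation networks with suboptimal sub-network extraction; and
    weighted-histogram (WHAM) free-energy reconstruction from
    umbrella-sampling windows with cumulative convergence diagnostics.
    Includes synthetic trajectory, Langevin, umbrella-sample and
    resistor-graph generators with known ground truth so every stage is
    testable without molecular-dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    MASS,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
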