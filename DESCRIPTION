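Package: pulsekin
Title: Pulsed-Swimming Kinematics and Phylogenetic Comparative Analysis
    of Medusae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the pulsed swimming of scyphozoan
    jellyfish from digitized trajectories and for comparative analysis of
    the resulting kinematic traits.  Computes per-frame bell fineness,
    displacement, velocity and Reynolds number; detects pulsation cycles
    and splits them into contraction, relaxation and interpulse phases to
    quantify passive energy recapture; fits BIC-selected ontogenetic
    scaling models against bell diameter and builds size-normalized
    species trait tables via allometric residuals; screens trait
    correlations and ordinates species by principal components; and
    estimates Blomberg's K phylogenetic signal (with a randomization
    test) and maximum-likelihood ancestral character states under
    Brownian motion on a user-supplied tree.  A synthetic pulsed-swimmer
    and Brownian-motion trait generator provides ground-truthed data for
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
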