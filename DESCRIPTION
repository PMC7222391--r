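Package: eegmst
Title: Minimum Spanning Tree Analysis of EEG Phase Lag Index Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Functional connectivity analysis of multichannel EEG using the
    phase lag index (PLI) and minimum spanning tree (MST) topology. Builds
    32-channel PLI matrices per frequency band (theta, alpha, beta1, beta2,
    gamma), extracts the maximum-weight spanning tree with Kruskal's
    algorithm, and computes tree statistics (mean PLI, maximum degree,
    maximum betweenness centrality, leaf fraction, diameter, eccentricity,
    tree hierarchy). Includes cross-subject average spanning trees with hub
    tables, a 2x2 (arousal x valence) within-subject ANOVA with paired
    contrasts and false discovery rate correction, and a synthetic
    phase-coupled oscillator generator that produces whole studies with
    known ground-truth coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
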