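Package: gazetherm
Title: Thermodynamic Analysis of Collective Gaze Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse collective eye-movement behaviour of groups of
    viewers watching the same video. From multi-viewer gaze trajectories the
    package computes inter-subject correlations of gaze position and movement
    direction, infers pairwise viewer "interactions" by fitting a
    maximum-entropy (fully connected XY) model with Monte Carlo Boltzmann
    learning, locates the critical temperature from heat-capacity curves over
    a temperature sweep, and characterises community structure (modularity) of
    the thresholded interaction network, together with rating-homophily
    statistics. A synthetic-data generator produces gaze panels, direction
    series and preference ratings with planted coupling structure, missing-data
    episodes and tunable rater agreement, so the full pipeline is testable
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
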