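Package: segbayes
Title: Segmental Bayesian Estimation of Network Conductances from Spike Trains
Version: 0.1.0
Authors@R: person("segbayes", "developers", role = c("aut", "cre"),
    email = "segbayes@example.org")
Description: Estimates the inhibitory (g_i) and gap-junctional (g_c)
    conductance of an electrically coupled neuronal network from spike
    trains.  Spike recordings are cut into short segments, a 68-component
    feature vector (firing rate, local variation, auto- and
    cross-correlograms, minimal-distance histogram, SPIKE-distance) is
    computed per segment, mutual-information ranking and PCA compress the
    features to a 3-D score, and a simulation library on a discrete
    (g_i, g_c) grid provides per-cell Gaussian-mixture likelihoods fitted
    by variational Bayes.  Conductances are then estimated by a
    hierarchical (segmental) Bayesian model that lets per-segment
    parameters jitter around one neuron-level value under pharmacological
    commonality constraints, by its non-segmental reduction, and by a
    minimum-distance baseline.  Includes a surrogate network simulator
    and renewal-process fixture generators for fully synthetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
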