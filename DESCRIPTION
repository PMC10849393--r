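Package: matchctl
Title: Spike-Train Matching and Short-Term Potentiation as Sparse Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the match-and-control mechanism, in which a pyramidal
    neuron compares a somatic spike train (a query) with the spike trains of
    many presynaptic axons (keys) through NMDA-receptor-gated calcium entry
    into dendritic spines, and a transient Hebbian potentiation lets the best
    matching axon drive the soma (transmitting its value). Provides a reduced
    biophysical spine simulator (back-propagating action potential and EPSP
    voltage kernels, magnesium-block gating, calcium dynamics and a
    fourth-power calcium detector), a bilinear temporal-kernel model of the
    detector with least-squares fitting, threshold calibration to a
    family-wise null rejection rate, ROC/true-positive-rate analyses with
    spike-time jitter, a lagged potentiation sigmoid with a reduced control
    phase, and an exact sparse hard-attention oracle for equivalence testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
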