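Package: neuroddm
Title: Single-Trial EEG Decoding and Neurally Informed Hierarchical
    Drift-Diffusion Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Links single-trial EEG evidence to decision dynamics in a
    two-alternative forced-choice task. Provides sliding-window linear
    discriminant decoding of stimulus categories with leave-one-trial-out
    cross-validated ROC area (Az), forward-model scalp topographies and
    permutation significance thresholds; k-means/silhouette partitioning of
    the significant decoding period into temporally distinct Early and Late
    components; group-level percentile-bootstrap cluster inference on Az
    differences between unisensory and multisensory conditions; robust
    percentage-bend correlations and ex-Gaussian mixture tests of reaction
    time bimodality; and a hierarchical Bayesian drift-diffusion model in
    which trial-wise component amplitudes regress the drift rate, with
    Wiener first-passage-time likelihood, Gelman-Rubin diagnostics and DIC
    model comparison. A synthetic-data module generates balanced sessions
    (design, diffusion-model behaviour, coupled multichannel EEG epochs)
    with the statistical structure the analysis assumes, so that every
    stage is testable end to end without external recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    mclust,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
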