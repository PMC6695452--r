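Package: dopacost
Title: Cost-Modulated Dopamine Reward Prediction Error Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how effort cost
    modulates dopamine reward-prediction-error signalling and stimulus-reward
    learning in a primate saccade paradigm. Generates synthetic task event
    streams, softmax/delta-rule choice sequences, gaze traces and
    inhomogeneous-Poisson spike trains with known ground truth; extracts
    saccadic reaction times with a 5-standard-deviation onset rule; fits
    cumulative-exponential learning curves and Rescorla-Wagner models with
    condition-specific learning rates by maximum likelihood; quantifies
    spike-train responses with Gaussian-kernel spike density functions,
    baseline-normalized window rates and auROC condition contrasts; and runs
    signed-rank, t-test and log-ratio inference over sessions and neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
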