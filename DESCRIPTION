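Package: gogoassay
Title: Analysis of Go-to/Go-away Auditory Discrimination Assays in Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Go-to/Go-away ("Go/Go") conditioned approach-avoidance
    paradigm, in which a fish learns to swim toward a screen after a rewarded
    sound cue and away from it after an aversive one. The package synthesizes
    the two complex sound stimuli (a noise-embedded multiharmonic tone train and
    a downward frequency-modulated sweep train), simulates conditioned swim
    trajectories with run-wise learning, attention oscillation and post-aversive
    hysteresis, reads and segments markerless-tracking tables into trial epochs,
    extracts the assay's kinematic features (distance from screen, swim
    activity, directional bias, longest-trajectory direction), detects the
    decision zone from cue-conditional positional densities, and runs the
    inference layer: Fisher discriminant analysis with Wilks' lambda,
    exact/asymptotic Wilcoxon tests with rank-biserial effect sizes, Cohen's d,
    Brown-Forsythe variance tests, ROC AUC, and the state-space dispersion
    (covariance trace) measure of overnight memory consolidation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
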