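Package: stressfc
Title: Source-Level EEG Power, Envelope Connectivity and Cardiac Responses
    Under Acute Psychosocial Stress
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for two-condition (control vs.
    negative feedback) psychophysiology experiments: relative EEG band power
    with 1/f spectral correction, orthogonalized amplitude-envelope-correlation
    functional connectivity between cortical regions of interest, event-related
    inter-beat-interval (IBI) responses from R-peak trains, and a mixed-model
    statistical layer with AIC family selection, BIC-based Bayes factors and
    Benjamini-Hochberg false-discovery-rate control. Includes a synthetic-data
    generator with known ground truth (band-limited oscillations with
    log-normal amplitude envelopes, controlled envelope coupling, linear
    channel mixing to emulate spatial leakage, condition-dependent cardiac
    acceleration and gamma-distributed questionnaire scores) so that every
    stage of the pipeline can be validated without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
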