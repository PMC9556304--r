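Package: spikeburst
Title: Burst Segmentation and Sensory-Response Analysis for Population Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for population spike-train recordings with
    synchronous bursting dynamics: sliding-window firing-rate estimation and
    z-scoring, two-state hidden Markov model segmentation of population
    activity into bursts and silent periods (Baum-Welch fitting, Viterbi
    decoding, burst statistics), stimulus-evoked modulation testing with
    Wilcoxon signed-rank pre/post comparisons and latency-to-peak estimation,
    optotagging classification of light-responsive units, and operant
    conditioning preference and learning metrics.  Includes a synthetic-data
    generator with ground truth so that every analysis stage can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
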