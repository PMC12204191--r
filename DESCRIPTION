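Package: gazemem
Title: Eye-Tracking Analysis of Visual Associative Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for eye-tracking studies of visual associative
    memory with a cue-target-lure retrieval task. Provides a synthetic cohort
    generator (healthy controls and temporal lobe epilepsy patients) with
    ground-truth oculomotor events, gaze session input/output and trial
    quality control, adaptive velocity-threshold saccade and fixation
    detection, per-trial scanning features (dwell ratios, scanpath entropy,
    first-target-fixation latency, between-object saccades), event-locked
    pupillometry with session z-scoring, nonparametric statistics (rank-sum
    tests, Benjamini-Hochberg correction, cluster-based permutation tests),
    and cross-validated linear support-vector decoding of trial accuracy and
    diagnosis with permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
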