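Package: optopeth
Title: Spike-Train, Optogenetic-Tagging, Fiber-Photometry and Licking
    Analysis for Head-Fixed Pavlovian Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolbox for head-fixed probabilistic Pavlovian
    conditioning experiments combining extracellular tetrode recordings,
    optogenetic tagging and bulk calcium fiber photometry. Provides
    peri-event time histograms with baseline z-scoring, Mann-Whitney
    response classification, autocorrelograms with burst-index and
    inter-spike-interval burst segmentation, K-means clustering of
    z-scored response profiles on principal components, spike-sorting
    quality metrics (isolation distance, L-ratio) and duplicate-unit
    detection, a stimulus-associated spike-latency test (SALT) based on
    Jensen-Shannon divergence for optogenetic identification,
    an isosbestic-corrected dF/F photometry pipeline with zero-phase
    Butterworth filtering, lick-based behavioral readouts with auROC
    permutation time-courses, and a synthetic-session generator that
    emulates the task's trial structure, event-locked spiking, tagging
    epochs and two-channel photometry signals for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
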