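Package: backconn
Title: Background Connectivity Analysis of Task fMRI with a Ground-Truth Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for measuring task-state ("background") functional
    connectivity between regions of interest after removing stimulus-evoked
    responses and nuisance signals, built around a blocked 2x2 (training
    timescale by action predictiveness) cue-action-outcome fMRI design.
    Implements the full analysis chain: experimental design construction and
    BIDS-style events serialization; a synthetic multi-run BOLD generator in
    which evoked responses are linearly superimposed on condition-coupled
    intrinsic fluctuations with known ground truth; discrete-cosine high-pass
    filtering, nuisance regression, finite impulse response (FIR)
    deconvolution, and event-related double-gamma GLMs; windowed, time-lagged,
    across-run control, ROI-dilation, and voxelwise connectivity variants with
    Fisher z transforms; multivoxel pattern similarity with trial-count
    balancing and a resampled split control; choice-RT and verbal-test
    behavioral summaries; and group inference including repeated-measures
    ANOVA contrasts, threshold-free cluster enhancement (TFCE), and sign-flip
    permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
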