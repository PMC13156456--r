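Package: hplvpool
Title: Quantification of Left-Ventricular Blood-Pool Hyperpolarized
    [1-13C]Pyruvate Signal by Exponential Rank-Intensity Modeling and
    Adaptive Thresholding
Version: 0.1.0
Authors@R:
    person("hplvpool", "developers", email = "hplvpool@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the left-ventricular (LV) blood-pool
    hyperpolarized [1-13C]pyruvate signal in dynamic cardiac 13C
    spectroscopic imaging. The sorted voxel-intensity distribution of the
    summed pyruvate image inside the endocardial region of interest is
    fitted with a single-parameter exponential rank-decay model; the fitted
    decay constant drives an adaptive, study-specific intensity threshold
    that excludes low signal-to-noise voxels. Normalized delivery metrics
    (decay constant or peak intensity over the thresholded mean-SNR area
    under the curve) are swept across thresholds at the cohort level and
    correlated against the downstream metabolic outcome (myocardial
    lactate plus bicarbonate) to locate the optimal threshold range.
    Includes elliptical ROI construction, k-space zero-fill interpolation,
    flip-angle correction, baseline noise estimation, SNR time curves, a
    synthetic phantom generator emulating the cohort structure, percentile
    and peak-intensity baseline models, model-comparison statistics, and a
    command-line pipeline with NIfTI-1 and JSON/CSV round-tripping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
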