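Package: alphabold
Title: EEG-Informed fMRI Analysis of Alpha-Band Power / BOLD Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for simultaneous resting-state
    EEG-fMRI analysis of occipital alpha-band power coupling with the BOLD
    signal. Covers MR gradient and ballistocardiogram artifact removal by
    average-artifact subtraction, complex-demodulation band-power
    estimation, construction of hemodynamically convolved power regressors,
    voxel-wise first-level general linear models with signed t-contrasts,
    and covariate-adjusted group inference with cluster-extent
    thresholding. Ships a synthetic simultaneous EEG-fMRI cohort generator
    with known envelope/BOLD coupling so that every stage is testable by
    parameter recovery without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    signal,
    igraph,
    jsonlite,
    tibble,
    withr,
    generics,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
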