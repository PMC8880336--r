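Package: pcflow
Title: Phase-Contrast MRI Flow Quantification and Resolution Error Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification pipeline for time-resolved
    phase-contrast (4D flow) MRI of small vessels. Generates analytic
    pulsatile velocity fields in cylindrical tubes, voxelizes them through
    velocity-to-phase encoding with complex partial-volume averaging, noise
    and compressed-sensing-style k-space undersampling, then quantifies flow
    with background-phase correction, lumen masking, aliasing correction and
    ROI integration. Provides comparison metrics (percentage flow difference,
    normalized RMS, repeatability coefficient) keyed to the number of voxels
    per vessel diameter, velocity-magnitude histograms, and the accompanying
    nonparametric statistical battery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
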