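Package: rgbtresp
Title: Contactless Respiratory Rate Estimation from Paired Visible and Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates respiratory rate (RR) from synchronized visible and
    thermal (RGB-T) video without contact sensors. The visible stream drives
    facial-landmark-based nostril region-of-interest (ROI) selection with a
    tracking-by-detection loop; a two-phase registration (checkerboard-rig
    scale adjustment followed by phase-congruency keypoint matching with a
    fast-sample-consensus affine fit) maps the ROI into the thermal stream;
    the mean-ROI thermal series is despiked (Hampel), smoothed, bandpass
    filtered (2nd-order Butterworth) and analysed in 30 s sliding windows by
    a chirp-Z transform to produce breaths-per-minute estimates. Includes
    agreement metrics (average absolute error, error standard deviation,
    Bland-Altman limits, Pearson correlation), a ground-truthed synthetic
    RGB-T scene generator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
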