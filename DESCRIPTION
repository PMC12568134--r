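Package: fallwin
Title: Sub-Window Statistical Features for Smartphone Fall Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Windowed statistical feature engineering for tri-axial
    accelerometer fall detection. Segments 3 s motion windows into
    overlapping sub-windows, extracts a named bank of per-axis statistics
    (mean, median, standard deviation, skewness, kurtosis, extremes) plus a
    cross-axis range norm, and feeds the resulting feature vectors to
    1-nearest-neighbour or RBF-kernel SVM detectors. Includes SMOTE class
    balancing restricted to training folds, k-fold / leave-one-subject-out
    cross-validation harnesses, a causal streaming evaluation protocol with
    OR-rule event scoring, sampling-based Shapley feature attribution, and a
    synthetic fall / activities-of-daily-living signal generator so the full
    pipeline is testable without sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    e1071,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
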