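Package: mridose
Title: Commissioning Statistics for MRI-Only Radiotherapy Dose Calculation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for commissioning MRI-only radiotherapy dose calculation
    against a CT reference. Implements bulk electron-density/HU override maps
    (unit, bulk-bone, bulk-bone-plus-air-cavity), exact cumulative dose-volume
    histogram computation with ICRU 83 style DVH points (D2%, D98%, Dmedian,
    Dmean, Dmax, DxCm3, VxGy), cohort statistics on percentage dose differences
    with respect to CT (one-way ANOVA, Tukey HSD, conservative mean +/- 2 SD
    intervals, assumption checks, noncentral-t power analysis), a cohort
    reliability criterion (95% of patients within a 2% dose tolerance) with
    quadrature uncertainty budgeting, and a synthetic-data generator that
    emulates paired CT/MRI dose distributions and cohort DVH-point tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    RNifti,
    jsonlite,
    readr,
    utils
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
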