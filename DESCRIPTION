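Package: noxlux
Title: Rest-Activity Rhythms and Sleep-EEG Analysis Under Dim Light at Night
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for rodent rest-activity and sleep-EEG studies of
    dim-light-at-night (DLAN) exposure: folded (chi-square style) periodogram
    estimates of circadian period and rhythm strength, detrended fluctuation
    analysis (DFA) of locomotor activity with a 3-8 h circadian scaling fit,
    4-s epoch EEG spectral analysis (0.25-25 Hz) with artifact flagging,
    rule-based WAKE/NREM/REM vigilance-state scoring and aggregation
    (state-percentage timecourses, waking peak, day-night amplitude, NREM
    slow-wave-activity timecourses), sleep-deprivation rebound comparisons,
    and the accompanying fixed-effects ANOVA, Bonferroni-corrected t-test and
    regression layer. A synthetic-data module simulates light:dark versus
    light:DLAN mouse study arms with known ground truth (1/f^beta fractal
    activity, per-phase Markov hypnograms, state-specific EEG spectra driven
    by a two-exponential sleep homeostat, and a 6-h forced-wake intervention)
    so every stage of the pipeline is verifiable end to end.
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
    generics,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
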