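Package: prosodyscreen
Title: Transcript-Free Prosodic Analysis for Mild Dementia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic prosodic analysis of read speech aimed at
    screening for mild dementia. Detects syllable nuclei directly from the
    energy envelope of the waveform (no transcript needed), tracks fundamental
    frequency with a normalized cross-correlation pitch tracker with
    dynamic-programming smoothing, derives twelve prosodic timing and F0
    features per recording, ranks features between diagnostic groups with an
    exact two-sample Kolmogorov-Smirnov test, and evaluates feature subsets
    with leave-one-out cross-validated support vector machines, including an
    exhaustive subset search. Includes seeded generators for synthetic
    syllable-train audio with analytic ground truth and for synthetic
    two-group prosodic feature cohorts, so the whole pipeline can be
    exercised end to end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
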