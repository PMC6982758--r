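Package: valphys
Title: Multimodal Physiological Analysis of Emotional Valence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying emotional valence (positive versus negative
    affect) from simultaneously recorded central and peripheral physiological
    signals: EEG spectral band power and hemispheric asymmetry indices, heart
    rate variability (19 time-domain, frequency-domain and Poincare measures
    computed from artifact-corrected inter-beat intervals), and wrist skin
    temperature cleaned by a scaled-MAD outlier rule. Includes nonparametric
    group statistics with gender splits, simulated-annealing wrapper feature
    selection scored by cross-validated classifiers, subject-dependent and
    leave-one-subject-out valence classification with KNN and QDA over
    configurable modality subsets, and a synthetic multi-subject data
    generator that emulates the statistical structure of a video-stimulation
    valence study so the full pipeline is testable without access to raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    MASS,
    class,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
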