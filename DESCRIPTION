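Package: disconnectome
Title: Longitudinal Structural Disconnectome Analysis from Lesion Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies lesion-induced white-matter disconnection against a
    reference streamline connectome and tracks its evolution over time.
    Given binary lesion masks at multiple timepoints, a labeled parcellation
    with resting-state-network assignments, and a healthy streamline set,
    the package computes per-edge disconnection and spared fractions,
    patient-weighted and binary connectivity matrices, within- and
    between-network vulnerability percentages, a three-way longitudinal
    edge-change classification (disconnections, re-emerging connections,
    over-connections), edge-level substantial-change analysis with a
    5th-percentile baseline floor, and a threshold sensitivity sweep.
    A synthetic-cohort generator with exact ground truth makes the whole
    pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
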