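Package: pepstep
Title: Single-Trial Analysis of Cortical Responses to Balance Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing perturbation-evoked cortical responses and
    reactive stepping behaviour from combined EEG and force-plate recordings.
    Detects reactive steps from vertical ground reaction forces, conditions and
    epochs continuous EEG, estimates source-resolved activity by independent
    component analysis with automatic selection of the midfrontal N1 component,
    extracts single-trial N1 amplitude and latency together with
    FWHM-parameterised Morlet wavelet time-frequency features, and relates them
    to perturbation intensity and stepping behaviour through a pooled
    mass-univariate linear model with Benjamini-Yekutieli false discovery rate
    control. A synthetic-data generator with known ground-truth effect
    structure makes every stage testable without access to laboratory
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ica,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
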