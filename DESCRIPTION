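Package: actiFLM
Title: Functional Linear Modeling of Collar-Mounted Actigraphy in Companion Dogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of 24-hour rest-activity rhythms from 1-minute epoch
    accelerometer counts. Converts per-subject multi-day activity records into
    smooth 24-hour periodic functions via Fourier-basis least squares, tests
    covariate effects across the day with a pointwise permutation F-test
    (observed F statistic against a permutation-derived critical-value curve),
    and models log day/night activity with linear mixed models followed by
    all-subsets AIC conditional model averaging. A synthetic cohort generator
    produces actigraphy records with known diurnal structure and known
    covariate effects for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    lme4
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'actiFLM-package.R'
    'classify.R'
    'flm.R'
    'fourier.R'
    'io.R'
    'lmm.R'
    'pipeline.R'
    'plots.R'
    'simulate.R'
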