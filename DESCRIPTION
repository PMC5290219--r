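Package: sncnirs
Title: Sigmoid Normal-Form Classification of Mental Workload from NIRS Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-parametric prediction of n-back working-memory load (1-back
    vs 2-back) from four-channel near-infrared spectroscopy (NIRS) time
    series. Implements the Sigmoid Normal-form Classifier (SNC): class-wise
    rescaling by the expected ratio of dissimilarity between task spaces,
    geometric medians computed by Weiszfeld iteration, a one-step
    normal-equation regression, and a sigmoid decision boundary anchored at
    the midpoint of the class medians. Ships the accompanying preprocessing
    chain (baseline normalization, Butterworth bandpass, linear and
    polynomial detrending), four per-channel feature families (signal mean
    and slope, contrast-to-noise ratio, moving average, differential
    entropy), a subject-wise percentage-wise cross-validation harness with
    baseline classifier adapters, and a synthetic fNIRS cohort generator for
    end-to-end testing without access to recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    MASS,
    class,
    e1071,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
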