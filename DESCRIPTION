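Package: akiwarn
Title: Self-Correcting Recurrent Networks for Early Warning of Acute
    Kidney Injury in ICU Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains and evaluates recurrent neural networks that feed their
    own lagged predictions, together with the later-observed true labels,
    back into every recurrent layer ("self-correcting" feedback), for
    6-hour-ahead prediction of acute kidney injury (AKI) from hourly ICU
    time series.  Implements the urine-output RIFLE labeling rule
    (rate < 0.5 mL/kg/h sustained for 6 h), an input-prediction
    regularizer, a urine-output regression variant, and the stop-gradient
    rule that keeps future losses from leaking into past predictions.
    Includes a seeded synthetic ICU cohort simulator with latent renal
    dynamics, hourly-grid preprocessing with inverse-distance imputation
    and cohort min-max normalization, weighted losses, Adam training with
    gradient clipping, stay-level cross-validation, and a gradient audit
    of the feedback loop.  All forward and backward passes are explicit
    matrix computations with no external deep-learning runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
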