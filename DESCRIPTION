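Package: akitv
Title: Interpretable 48-Hour-Lead Prediction of Hospital-Acquired Acute
    Kidney Injury from Longitudinal Laboratory Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and stages acute kidney injury (AKI) episodes from
    serial serum creatinine under the KDIGO 2012 creatinine criteria,
    assembles leakage-safe supervised samples from irregular longitudinal
    laboratory data (48-hour prediction window, 7-day feature window with
    daily binning, min-max normalization and zero imputation), and fits an
    interpretable time-invariant/time-variant (TITV) recurrent risk model
    combining feature-wise linear modulation, a bidirectional gated
    recurrent network and factorized self-attention, so that every risk
    score decomposes exactly into per-feature, per-window additive
    contributions. Includes logistic and (bidirectional) GRU baselines,
    threshold-sweep evaluation with bootstrap confidence intervals for the
    AUROC, CKD-EPI 2009 eGFR computation, a five-rule admission exclusion
    cascade, and a synthetic electronic-health-record generator with
    planted AKI episodes and archetype-specific prodromal signals for
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
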