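Package: edmweb
Title: Empirical Dynamic Modelling of Interaction Webs from Replicated Short Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs species interaction networks and time-varying
    per-capita interaction effects from replicated short ecological time
    series using empirical dynamic modelling (EDM). Provides composite
    (multi-fragment) time-delay embedding, simplex projection with
    leave-one-out cross-validation, convergent cross mapping (CCM) with a
    three-criterion acceptance cascade (convergence, seasonal-surrogate
    significance, lagged-CCM screening), regularized multivariate S-maps
    for tracking per-capita interaction effects through time, summaries of
    interaction density-dependence and temporal variability, and
    mixed-model regressions of population sensitivity to press
    disturbances on those interaction properties. A mesocosm-style
    community simulator with known interaction Jacobians supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    glmmTMB,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
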