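Package: hardivine
Title: Machine-Learning Prediction of Grapevine Bud Cold Hardiness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts grapevine dormant-bud freezing tolerance (bud LT50, the
    lethal temperature for half of a bud population) from air-temperature
    records and cultivar identity. Provides hourly-temperature estimation
    from daily minima and maxima, engineering of a 117-column feature set
    (one-hot cultivar indicators, daily and cumulative temperature
    descriptors, chilling accumulation under the Utah, North Carolina and
    chilling-hours models, growing degree hours, and exponentially weighted
    moving-average temperatures in both forward and reversed-window form), a
    bagged and stacked weighted-ensemble regression trainer with
    least-complexity model selection, permutation and Shapley feature
    importance, a sigmoid freezing-damage-potential transform for deployment,
    and a synthetic multi-season weather and hardiness generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rlang,
    withr,
    xgboost,
    ranger,
    glmnet,
    caret
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
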