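Package: aebimpact
Title: National-Level Safety Impact Evaluation of Automatic Emergency Braking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the national-level road-safety impact of the
    automatic emergency braking (AEB) system. Forecasts annual road-traffic
    fatalities and severe injuries with a GM(1,1) grey model corrected by a
    Markov chain on relative residuals, projects AEB fleet penetration from a
    Gompertz vehicle-ownership curve, stock-turnover new-vehicle sales and a
    policy-anchored new-vehicle penetration schedule, combines collision-type
    proportions with per-type collision-avoidance effectiveness, quantifies
    technical limiting factors (speed, weather, light, activation), and runs
    baseline / optimistic / pessimistic counterfactual scenarios with a
    single-factor sensitivity decomposition. Ships the 2017 Chinese
    collision-type and driving-condition tables and a synthetic-data generator
    so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
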