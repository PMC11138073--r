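Package: qmcea
Title: Quasi-Markov Cost-Utility Analysis of Family Therapy After Adolescent Self-Harm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Long-term cost-utility analysis comparing systemic family therapy
    with treatment as usual for adolescents seen after self-harm. Implements a
    three-state quasi-Markov cohort model whose per-cycle state-occupancy
    probabilities, conditional costs and utilities are estimated from
    hospitalisation records with generalized estimating equations, rolled up
    into discounted costs and quality-adjusted life years, and summarised via
    incremental cost-effectiveness ratios, net health benefit,
    cost-effectiveness planes, acceptability curves and probabilistic
    sensitivity analysis. Ships a synthetic two-arm trial generator emulating
    the statistical structure of the confidential source data, multiple
    imputation by predictive mean matching with Rubin's-rules pooling, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
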