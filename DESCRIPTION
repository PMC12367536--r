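Package: nsurplus
Title: Nitrogen Surplus Budgets, Regional Typologies and 2030 Reduction Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for regional soil-surface nitrogen (N) budgeting and scenario
    analysis of agricultural N surplus reduction in Europe. Computes total and
    agricultural N surplus and nitrogen use efficiency from component time
    series carried as a 16-member ensemble, classifies regions into four
    N-surplus typologies (manure-dominated, fertilizer-dominated, moderate,
    natural) with a 2x2 batch self-organizing map validated by the
    Davies-Bouldin index, fits one-parameter hyperbolic input-output yield
    response functions with linear technology-trend extrapolation of the
    response coefficient to 2030, and projects N surplus in 2030 under
    business-as-usual and named input-reduction scenarios as well as over the
    full fertilizer x manure reduction grid, reporting percent reductions
    against a 2015-2019 baseline and the EU Green Deal 50% reduction target.
    Includes a synthetic trajectory generator emulating the ensemble and
    typology structure of the historical data so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
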