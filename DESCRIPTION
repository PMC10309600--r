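Package: aeroyield
Title: Sampling-Design Statistics for Airborne Environmental DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for planning and evaluating filter-based
    bioaerosol DNA sampling. Models per-session DNA yields with a
    moment-matched skew-t distribution (closed-form moments and a
    deterministic conversion between direct and centred parameters),
    estimates the probability of reaching a target yield by parametric,
    empirical-CDF or kernel-density methods, estimates the minimal number
    of filter sheets needed via Poisson simulation, one-tailed lower
    confidence bounds and linear regression, ranks air-quality covariates
    by ROC-based importance around Fisher's linear discriminant analysis,
    quantifies PCR bands from gel images with equal-size rectangle masks,
    and ships seeded synthetic-data generators so every pipeline stage is
    testable without the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
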