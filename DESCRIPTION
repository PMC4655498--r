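Package: pphcca
Title: Cost-Consequences Analysis of Uterotonic Prophylaxis for Postpartum Haemorrhage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A deterministic cohort model for the economic evaluation of
    postpartum haemorrhage (PPH) prophylaxis strategies (oxytocin,
    misoprostol, or no treatment) across mixed hospital/community birth
    settings. Expected event counts are computed outcome-by-outcome as
    births x baseline rate x relative risk; costs follow a WHO
    Mother-Baby-Package-style treatment cascade with configurable unit
    costs and referral recipe. Includes a DerSimonian-Laird random-effects
    pooling routine for relative risks from 2x2 trial tables, one-way
    sensitivity analyses and a hospital/community mix sweep, and synthetic
    data generators (trial tables with between-trial heterogeneity,
    person-level Bernoulli cohorts) that serve as stochastic oracles for
    the deterministic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
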