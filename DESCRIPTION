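Package: lstconn
Title: Latent State-Trait Modelling of Test-Retest Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating trait, day-to-day state, and random error
    components of repeated resting-state functional connectivity (RSFC)
    measurements with latent state-trait structural equation models, and for
    propagating that measurement model into downstream analyses: maximum
    likelihood fitting of small structured covariance models (single-trait,
    multistate single-trait, method-factor, bi-factor, and congeneric
    families), variance decomposition into common consistency, occasion
    specificity and random error, omega composite reliability, disattenuated
    connectivity-phenotype correlations with improvement factors and power
    implications, factor-score ridge regression under repeated split-half
    cross-validation, and operative (conditional-normal) prediction under
    family-aware cross-validation. Includes a seeded synthetic-data generator
    emulating a four-scan, two-day test-retest design with known ground truth,
    and a desk-scale connectivity pipeline (volume dropping, spike regression,
    optional mean-signal regression, Fisher-z edge computation).
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
    optparse
Config/testthat/edition: 3
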