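Package: mrhet
Title: Genetically Driven Effect Heterogeneity in Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of genetically driven effect heterogeneity in
    Mendelian randomization using individual-level data. Implements the
    genetically moderated exposure effect (GMEE) family of estimators,
    including the robust RGMEE, together with two two-variant procedures
    that combine a homogeneity-violating moderator variant with a
    homogeneity-respecting instrument to recover group-specific causal
    effects. Also provides a Wald-ratio bias decomposition under a known
    data-generating process, a synthetic cohort simulator with latent
    potential-outcome ground truth, and a Monte-Carlo study engine
    reporting bias, power and coverage with Monte-Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
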