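Package: metstage
Title: Two-Stage Mixed-Model Prediction of Genotype Performance in Untested Locations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stage-wise analysis of plant-breeding multi-environment trials for
    predicting genotype performance in new, untested locations. Stage I fits a
    row-column linear mixed model per location and forwards adjusted genotype
    means with diagonal precision weights. Stage II fits weighted linear mixed
    models with the residual covariance fixed at the forwarded diagonal,
    supporting pedigree-based numerator relationship matrices for the genotype
    effects and identity, diagonal or factor-analytic covariance structures for
    the genotype-by-location interaction. Synthetic environmental covariates are
    extracted from large environmental-covariate panels by multivariate partial
    least squares and entered as fixed and random-coefficient regressions.
    Models are compared by leave-one-location-out cross-validation using the
    mean squared error of predicted differences and averaged Spearman rank
    correlations. Includes simulators for pedigrees, environmental covariates
    and trial phenotypes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    yaml
Config/testthat/edition: 3
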