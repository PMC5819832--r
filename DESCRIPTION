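Package: hidstats
Title: Clustered-Binomial Inference and Behavioral Track Analytics for
    C. elegans Dauer and Foraging Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference machinery for plate-based
    high-temperature-induced dauer-formation assays and adult foraging
    behavior in C. elegans. Provides generators for plate-clustered
    binomial assay data with day, plate, and culture-history variance
    components on the logit scale; four analysis routes for such data
    (Welch t-tests on plate proportions, one-way ANOVA, frequentist
    binomial GLMMs, and Bayesian binomial GLMMs with MCMC); Poisson
    mixed models for grid-entry exploration counts and Gaussian mixed
    models for log10-transformed fluorescence intensities; single-step
    multivariate-t (Dunnett/Tukey-type) multiplicity adjustment;
    likelihood-ratio tests for nested fits; a Monte Carlo study of
    type-I and type-II error across variance, balance, and bias
    conditions; and locomotion-track analytics (speed, three-frame
    angular velocity, 10-second binning, slope-based roaming/dwelling
    classification, and capped grid-entry exploration scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    mvtnorm,
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
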