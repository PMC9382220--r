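Package: bibquality
Title: Statistical Reporting Accuracy, Evidential Value and Replicability
    as Functions of Bibliometric Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing whether citation counts and journal impact
    factors predict indicators of research quality. Parses APA-formatted
    statistical test reports out of running text, recomputes p-values and
    classifies reporting inconsistencies and decision errors, scores the
    evidential value of significant tests with default Jeffreys-Zellner-Siow
    (JZS) Bayes factors computed from reported summary statistics, and links
    bibliometric predictors to error counts, evidence strength and
    replication success with hierarchical Bayesian models (zero-inflated
    Poisson with an exposure offset, beta regression, multilevel logistic
    regression) fitted by MCMC through JAGS. Includes Savage-Dickey predictor
    Bayes factors, PSIS-LOO R-squared, posterior predictive checks, and a
    seeded synthetic literature-corpus generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
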