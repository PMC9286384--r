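Package: compclass
Title: Comparison-Class Inference for Gradable Adjectives via Rational
    Speech Act Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a family of Rational Speech Act (RSA) models of
    gradable-adjective interpretation in which the comparison class
    ("tall for a basketball player" vs. "tall for a person") is inferred
    jointly with the degree, together with the joint Bayesian data
    analysis that fits world-knowledge degree priors and
    comparison-class-prior parameters to two behavioral tasks
    (free-paraphrase comparison-class inference and adjective
    endorsement). Provides four parameterizations of the
    comparison-class prior (flat, basic-level bias, NP-frequency effect,
    and their combination), a rival non-pragmatic literal-listener
    model, adaptive Metropolis-within-Gibbs sampling, annealed
    importance sampling for marginal likelihoods and Bayes factors,
    posterior predictive checks and fit metrics, plus a synthetic-data
    generator that emulates the behavioral study design for parameter-
    and model-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
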