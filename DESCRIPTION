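Package: asrcycle
Title: Trial-Level Models of the Attribution-Self-Representation Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for studying reciprocal,
    trial-by-trial interactions between causal attributions and beliefs
    about one's own skill. Provides an agent simulator coupling a
    sigmoidal attribution rule with attribution-gated Rescorla-Wagner
    skill updating; a synthetic-task generator emulating a
    staircase-controlled maze game with interleaved attribution and
    skill-report probes; Rescorla-Wagner model families for skill
    reports and softmax linear models for attribution choices with
    exact likelihoods; hierarchical Bayesian fitting by adaptive
    Metropolis-within-Gibbs with WAIC model comparison and parameter
    recovery harnesses; and model-agnostic permutation statistics
    (within-participant paired-t and repeated-measures interaction-F
    permutation tests, Hedges' corrected d, quartile discretisation,
    Benjamini-Hochberg correction, correlation permutation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
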