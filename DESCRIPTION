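Package: smpassoc
Title: Semi-Markov Process Models of Free Association and Narrative
    Coherence Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for computational analyses of disorganized thinking.
    Implements a semi-Markov process (SMP) model of free-association
    generation and executive regulation -- a tempered typicality-based
    generation distribution, a regulated accept/reject stage, gamma
    generation times linked to surprisal, and uniform non-decision time --
    together with the joint density of a reported association and its
    reaction time, forward simulation, and hierarchical
    importance-sampling expectation-maximization fitting with
    integrated-BIC model comparison. Also provides free-association norm
    construction (typicality, idiosyncrasy, validity filtering),
    natural-language metrics for free narratives (TF-IDF narrative
    typicality and multi-scale semantic coherence via aggregated-vector
    cosine or relaxed word mover's distance), and a synthetic-data
    generator producing cue norms, cohorts with known parameters,
    simulated trials, embedding spaces, and drifting narrative corpora
    for end-to-end parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
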