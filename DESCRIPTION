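Package: hrbnet
Title: Co-Occurrence and Network Clustering of Binary Health-Risk Behaviors
Version: 0.1.0
Authors@R:
    person("Maintainer", "hrbnet", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how binary health-risk behaviors (inadequate
    sleep, insufficient fruit and vegetable intake, salty diet, smoking,
    drinking, irregular exercise) co-occur and cluster in survey data on
    older adults. Provides dichotomous behavior coding from raw survey
    responses, prevalence and behavior-count descriptives, observed-to-
    expected (O/E) ratio clustering statistics with bootstrap confidence
    intervals, Ising network estimation by nodewise L1-penalized logistic
    regression with extended-BIC model selection (eLasso), bootstrap and
    case-dropping stability assessment, Louvain community detection, and a
    fully synthetic survey generator that samples exactly from a
    parameterized 7-node Ising model with planted covariate effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
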