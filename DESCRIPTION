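Package: themescan
Title: Keyword Theme Scoring and Topic Modeling of Cancer-Survivor Forum Posts
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dictionary-based content coding of health discussion-board
    corpora: a built-in psychosocial-survivorship keyword lexicon with
    root-prefix and phrase matching, per-post theme scores and threshold
    classification, corpus descriptives (board composition, theme prevalence
    by year, top-word tables), qualitative-sample selection with a per-user
    cap, latent Dirichlet allocation fit by collapsed Gibbs sampling with
    C_V coherence model selection and lambda-weighted relevance ranking of
    topic terms, and a synthetic-corpus generator with planted themes and
    latent topics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
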