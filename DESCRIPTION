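Package: forumcondense
Title: Topic Modeling, Sentiment Scoring, and Percentile Condensation of
    Health-Forum Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A sequential NLP-to-qualitative workflow for characterizing
    unstructured user-generated content from peer-support forums in mobile
    health interventions. Builds dual analysis corpora from a forum export,
    fits and refines latent Dirichlet allocation topic models with a
    collapsed Gibbs sampler, scores post valence with a rule-based
    social-media-aware lexicon method, condenses each topic and valence
    stratum to the posts strictly above a percentile threshold of
    topic-token affinity or polarity, exports coder-ready files, and
    computes pooled intercoder reliability. Includes a synthetic
    forum-corpus generator with planted topic and sentiment structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
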