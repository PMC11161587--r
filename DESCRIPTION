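Package: kdtlab
Title: Decision-Making Assessment Analytics for Serious-Game Behavioral Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for validating a serious-game
    decision-making assessment (the Kalliste Decision Task) against classical
    instruments. Provides a synthetic-cohort generator calibrated to published
    cluster profiles, a prospect-theory model of the mixed gamble task with
    per-subject maximum likelihood and hierarchical Bayesian estimation
    (random-walk Metropolis-within-Gibbs, split-chain Gelman-Rubin
    diagnostics), Iowa Gambling Task and questionnaire scoring, screening
    statistics (3-SD outliers, Monte-Carlo Lilliefors normality, partial
    Pearson correlations), Ward-linkage behavioral phenotyping with
    silhouette-based model selection and K-means confirmation, and
    MANCOVA group comparisons with partial eta squared and Bonferroni
    post hocs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
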