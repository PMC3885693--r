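Package: rdsmix
Title: Contact-Network Analysis for Respondent-Driven Sampling Diary Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing one-day contact-diary surveys collected by
    respondent-driven sampling (RDS). Reconstructs recruitment forests from
    recruiter-recruit records, derives censored contact degrees from diary
    counts, fits a negative binomial degree distribution by maximum
    likelihood, measures attribute assortativity between participants at any
    tree distance (Pearson, phi and Spearman coefficients with distance
    lumping), estimates between- and within-component variance and the
    intraclass correlation from an intercept-only two-level model by REML,
    computes Volz-Heckathorn (RDS-II) population proportion estimates and
    sample-composition diagnostics over recruitment waves, and tests the
    first-order Markov assumption by Monte-Carlo simulation of an
    autoregressive process on the recruitment trees. Includes a synthetic
    recruitment-forest generator (coupon-limited branching process with
    assortative attributes and negative-binomial degrees) so every analysis
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
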