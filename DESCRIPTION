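Package: wsscover
Title: Small-Area Estimation of Drinking-Water and Sanitation Coverage with
    Geographical Inequality Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian hierarchical spatially-explicit logistic modelling of
    household cluster-survey indicators of improved drinking water, improved
    sanitation and open defecation across nested administrative areas.
    Country-level random intercepts and linear time trends by urban/rural
    stratum are combined with intrinsic conditional autoregressive (ICAR)
    district effects and unstructured province effects, fitted by adaptive
    Metropolis-within-Gibbs MCMC.  Posterior prediction of coverage for a
    target year (including districts without data, via the ICAR conditional),
    population-weighted aggregation to national level, significance flagging
    of districts against the national mean, and population-weighted Lorenz
    curves, geographical GINI coefficients and relative geographic inequality
    (RGI) scores.  A synthetic-data module emulates DHS/MICS-style cluster
    sampling so the full pipeline is testable without licensed microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tools,
    stats,
    utils,
    tibble,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
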