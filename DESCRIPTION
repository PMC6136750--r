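Package: bayesvar
Title: Bayesian Multifactorial Prediction and Classification of Missense Variants
Version: 0.1.0
Authors@R:
    person("Dana", "Qiu", email = "dana.qiu@example.org", role = c("aut", "cre"))
Description: Gene-specific Bayesian logistic regression models of missense
    variant pathogenicity fit by Polya-Gamma Gibbs sampling over selected
    in silico predictor subsets, multifactorial posterior updating over
    likelihood-ratio evidence statistics, and five-tier variant
    classification (benign / likely benign / uncertain / likely pathogenic /
    pathogenic) from 95% probability credible intervals. Includes training
    data expansion for sparse genes, k-nearest-neighbour score imputation,
    leave-one-out cross-validation evaluation with rank-based AUC and
    DeLong comparison, and a synthetic multigene-panel generator for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
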