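Package: phenoGRN
Title: Phenotype-Relevant Gene Regulatory Network Inference from
    Expression and ChIP-Seq Summary Statistics
Version: 0.1.0
Authors@R:
    person("phenoGRN", "Developers", email = "phenogrn@example.org",
           role = c("aut", "cre"))
Description: Infers transcription-factor-to-gene regulatory networks that
    are relevant to a binary phenotype by integrating three channels of
    summary statistics: gene-phenotype differential-expression p-values,
    expression-based TF-gene pseudo p-values (Elastic Net selection
    followed by ordinary least squares), and ChIP-seq peak-to-gene
    distance p-values. A Bernoulli latent-edge probabilistic graphical
    model with Uniform/Beta(alpha, 1) mixture likelihoods and a truncated
    Normal hyperprior on edge density is fit by Markov chain Monte Carlo;
    per-gene negative controls, min-max normalization and three filters
    refine the posterior into a final network with confidence scores.
    Includes a synthetic-evidence generator with planted networks, an
    exact quadrature oracle for single-edge posteriors, and AUPRC-ratio
    evaluation against ground-truth edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
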