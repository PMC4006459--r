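Package: scanbma
Title: Fast Bayesian Model Averaging for Gene Regulatory Network Inference
    from Time-Series Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from time-series gene
    expression data by Bayesian model averaging (BMA) over lagged linear
    regression models.  For each target gene the candidate-regulator model
    space is explored with a fast active-set Occam's-window search, models
    are scored in closed form under Zellner's g-prior with informative prior
    edge probabilities, the g hyperparameter is estimated by an EM algorithm
    maximising the marginal likelihood over the model space, and posterior
    inclusion probabilities are refined so that every candidate edge gets a
    usable, strictly interior probability.  Includes the two data
    transformations (time adjustment against a shared perturbation
    trajectory, and removal of each gene's own autoregressive effect),
    network assembly and evaluation (precision, AUROC, AUPRC against a gold
    standard, optionally restricted to an evaluable regulator set), and a
    seeded simulator of sparse directed networks with linear-Gaussian
    autoregressive dynamics for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
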