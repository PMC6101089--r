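Package: onebitmc
Title: One-Bit Matrix Completion for Bipartite Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts unknown links in a bipartite binary relationship
    (such as microbe-disease associations) by one-bit matrix completion:
    a low-rank real-valued latent matrix is recovered from partially
    observed +1/-1 labels through a probit observation model, maximising
    the probit log-likelihood over a nuclear-norm ball by a nonmonotone
    spectral projected gradient method with singular-value
    soft-thresholding as the projection. Includes leave-one-out and
    k-fold cross-validation drivers with ROC/PR metrics, a (sigma, rank)
    grid search, a truncated-SVD imputation baseline, a generator for
    synthetic data drawn from the assumed model, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
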