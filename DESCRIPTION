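Package: protex
Title: Prototype and Exemplar Models of Human Categorization in High-Dimensional Feature Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits and compares prototype and exemplar models of human
    categorization over arbitrary real-valued stimulus embeddings, using the
    Luce-Shepard choice rule with Mahalanobis-style diagonal distance metrics.
    Models are estimated against per-stimulus distributions of human category
    guesses by mini-batch gradient descent with k-fold cross-validation and
    early stopping, and compared by cross-validated log likelihood, AIC,
    entropy-stratified rank correlations, second-best accuracy and a
    split-half noise ceiling. Also includes a Gaussian-mixture simulation
    study of how prototype and exemplar classifiers trade off with stimulus
    dimensionality and training-set size, and generators for synthetic
    embeddings and soft-label guess data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
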