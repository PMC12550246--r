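Package: leaffusion
Title: Multi-Level Handcrafted Feature Fusion for Leaf Image Classification
Version: 1.0.0
Authors@R:
    person("leaffusion", "developers", email = "leaffusion@example.org",
           role = c("aut", "cre"))
Description: A pipeline for classifying visually similar plant species from
    leaf photographs using fused handcrafted image descriptors: a joint 3-D
    RGB color histogram, rotation-invariant uniform local binary patterns,
    a Gabor filter bank, and histograms of oriented gradients, concatenated
    into one feature vector. Includes SMOTE minority oversampling in feature
    space, a cross-validated classifier suite (decision tree, random forest,
    gradient boosting, AdaBoost, k-nearest neighbours, Gaussian naive Bayes,
    multinomial logistic regression, RBF support vector machine) with a
    soft-voting ensemble, an inter-class cosine similarity diagnostic, a
    robustness stress-testing harness (noise, rescaling, rotation,
    occlusion), and a deterministic synthetic leaf-image generator used as
    a test fixture factory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    FNN,
    glmnet,
    jsonlite,
    jpeg,
    png,
    quadprog,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
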