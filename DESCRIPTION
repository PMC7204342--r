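Package: dbtseg
Title: Patch-Based U-Net Segmentation of Breast Masses in Digital Breast
    Tomosynthesis Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete, testable pipeline for automatic segmentation of
    breast masses in reconstructed digital breast tomosynthesis (DBT) slice
    stacks. Provides a synthetic DBT phantom generator (textured background,
    low-contrast ellipsoidal lesions, Poisson photon noise, two site
    profiles), morphological top-hat enhancement with a radial-basis
    constraint field, balanced patch extraction with right-angle rotation
    augmentation, a from-scratch valid-convolution U-Net trained with an
    F-beta overlap loss and the Adam optimizer, four patch-vote fusion
    schemes (majority, maximum probability, sum of probabilities,
    connectivity), connected-component size filtering with median boundary
    smoothing, and pixel-wise sensitivity/specificity/accuracy and ROC/AUC
    evaluation including a cross-site 5-fold cross-validation runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    tiff,
    png,
    jpeg
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
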