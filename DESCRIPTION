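Package: cropdx
Title: Crop Disease Diagnosis from Leaf Images with Diffusion Denoising,
    Fuzzy Segmentation, Metaheuristic Feature Selection and Graph
    Convolutional Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for diagnosing crop
    diseases from leaf images. Images are denoised by adaptive anisotropic
    diffusion whose conductance combines a Perona-Malik edge-stopping
    function with a local-variance modulation; lesions are segmented by a
    nested U-Net++ encoder-decoder augmented with Gaussian fuzzy
    memberships, Mamdani min-implication rules and centroid
    defuzzification; convolutional summary features are selected by a
    hybrid gorilla/remora population metaheuristic balancing holdout
    accuracy against feature redundancy; and the selected features are
    classified by a graph convolutional network built on a
    cosine-similarity feature graph.  A synthetic leaf-phantom generator
    with exact ground-truth masks makes every stage reproducible without
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
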