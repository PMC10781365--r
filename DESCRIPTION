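Package: sectorsal
Title: Sector-Discretized Evaluation of CNN Saliency Maps for Glaucoma
    Fundus Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate pixel-attribution (saliency) methods applied to
    convolutional classifiers of optic-nerve-head fundus images. Implements nine
    attribution algorithms (Gradient, Guided Backpropagation, SmoothGrad,
    SmoothGrad Squared, VarGrad, Integrated Gradients, Occlusion, GradCAM,
    ScoreCAM) against a small differentiable-model contract, discretizes each
    saliency map onto the seven anatomical optic-disc sectors (nasal, nasal
    inferior, temporal inferior, temporal, temporal superior, nasal superior,
    background) by thresholding at 75% of the map maximum, and analyses the
    resulting sector-score vectors: global sector-relevance probabilities
    grouped by predicted class, Spearman rank-correlation agreement between
    methods, folds and models, and the model-parameter and label randomization
    sanity checks used to discard unreliable attribution methods. Ships a
    synthetic fundus generator with known discriminative structure (cup-to-disc
    ratio and sector-localized rim loss) and a compact, fully inspectable
    convolutional network so the entire pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
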