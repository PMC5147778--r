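Package: popdim
Title: Dimensionality and Basis-Pattern Similarity of Neural Population
    Activity and Visual Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking how many dimensions trial-averaged neural
    population activity (or the pixel intensities of a visual stimulus)
    occupies, and whether the dimensions occupied under different conditions
    are the same.  Dimensionality is the number of principal components
    needed to reach a cumulative-variance threshold; subspace similarity is
    assessed with the pattern aggregation method, which concatenates the
    per-condition orthonormal basis patterns and counts the large singular
    values of the aggregate, compared against a Monte-Carlo chance level for
    randomly drawn subspaces and summarised by a similarity index and a
    permutation probability.  Includes time-resolved and growing-window
    analyses, procedural generators for drifting-grating and jittered
    white-noise movie stimuli plus a pink-noise natural-movie surrogate,
    parametric image manipulations (contrast, phase randomization, spectral
    flattening), a four-stage V1 receptive-field model (3-d Gabor filtering,
    untuned suppression, divisive normalization, pointwise nonlinearity),
    and a correlation-integral (fractal) dimensionality estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
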