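Package: flyhue
Title: Tetrachromatic Color Spaces, Hue Tuning and Connectome-Constrained
    Circuit Models for Drosophila Chromatic Neurons
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing chromatic tuning of neurons in the fruit-fly
    visual system. Builds a four-opsin (Rh3-Rh6) color space from photon
    captures, with hue/saturation coordinates on the isoluminant tetrahedron
    and a two-dimensional opponent projection; extracts and normalizes
    calcium-imaging response amplitudes with SNR filtering; computes tuning
    indices (sparsity, luminance invariance, hue sensitivity) with bootstrap
    confidence intervals and noise-corrected R-squared; fits three encoding
    models (linear, linear-nonlinear, and a von Mises-style nonlinear
    selectivity model with a kappa/alpha grid); and fits a twelve-neuron
    connectome-constrained recurrent rate model by Anderson-accelerated
    fixed-point solving with implicit differentiation, including synaptic
    silencing (TeNT) and recurrence-ablation perturbations, sign search and
    random-weight null distributions. A synthetic-data generator emulates
    gamut and contrast stimulus sets, LED intensity solving and dF/F traces
    so the full pipeline runs end-to-end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    signal,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
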