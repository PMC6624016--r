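Package: fluxmap
Title: Asymmetric Diffusion Map Modeling of Cyclic Neural Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts low-dimensional cyclic-flux dynamics from multivariate,
    noisy neuronal activity time series. Recordings are delay embedded into a
    reconstructed phase space, cast into a row-stochastic transition matrix via
    an asymmetric (forward-centered) diffusion kernel, and decomposed into
    trajectory loops via the leading complex eigenmode (phase) and
    maximum-modularity clustering of time-lagged row correlations (loop
    identity). The resulting (phase, loop) manifold supports simulation of
    novel activity, behavioral-state decoding, dwell-time statistics, and
    forecasting of behavioral transition times, together with template-based
    event decoding, behavioral-phase warping consistency tests, and KL-based
    relative information. Synthetic generators with known ground truth (a
    two-neuron stochastic relaxation oscillator, multi-loop noisy limit
    cycles, and a Markov behavior switcher) are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: TimeCourse, DimensionReduction, Clustering, Network
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'behavior.R'
    'diffusion.R'
    'embedding.R'
    'flux.R'
    'fluxmap-package.R'
    'io.R'
    'manifold.R'
    'pipeline.R'
    'preprocess.R'
    'simulate.R'
    'synthetic.R'
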