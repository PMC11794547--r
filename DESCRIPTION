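Package: maizeSPU
Title: Hyperspectral Estimation of Maize Shoot Phosphorus Uptake
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An organ-wise pipeline for estimating maize shoot phosphorus
    uptake (SPU, kg/ha) from canopy hyperspectral reflectance. Sensitive
    bands are selected by generalized two-dimensional correlation
    spectroscopy (2DCOS) on derivative spectra and by two-trace 2DCOS
    coupling of the filling and milk growth stages. Leaf biomass is
    retrieved by a hybrid inversion of a PROSPECT-5B + 4SAIL canopy
    radiative-transfer forward model whose simulated training pool is
    filtered by a Newton-Raphson-based-optimizer active-learning strategy
    (spectral- and response-distance constraints) before an extreme
    learning machine is fitted. Leaf, stem and grain phosphorus uptake are
    combined into a single shoot prediction. Includes EFAST global
    sensitivity screening, population metaheuristics, dual-band spectral
    indices, evaluation metrics, and a synthetic multi-treatment field
    campaign generator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    signal,
    lhs,
    ranger,
    e1071,
    xgboost,
    nnet,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Regression, Spectra, Agriculture
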