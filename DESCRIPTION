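Package: glycospec
Title: SWIR Hyperspectral Chemometrics for Glycoalkaloid Prediction in Potato Tubers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for predicting total glycoalkaloid (TGA)
    content of greening potato tubers from short-wave infrared (900-2500 nm)
    hyperspectral reflectance images. Provides ENVI hypercube input/output,
    reflectance calibration against white/dark references, Otsu masking and
    region-of-interest mean-spectrum extraction; spectral pre-processing
    (standard normal variate, Savitzky-Golay derivatives, orthogonal signal
    correction); NIPALS partial least squares and RBF support-vector
    calibration with leave-one-out and train/test evaluation (R2, RMSE, RPD);
    and wavelength selection by competitive adaptive reweighted sampling
    (CARS), iteratively retaining informative variables (IRIV) and greedy
    backward elimination. A synthetic-data module generates spectra,
    hypercubes and reference values with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071,
    EBImage,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'glycospec-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'synthetic.R'
    'hypercube-io.R'
    'preprocess.R'
    'regression.R'
    'feature-selection.R'
    'pipeline.R'
    'fixtures.R'
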