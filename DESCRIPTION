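Package: steatoFluor
Title: Steatosis Grading from Liver Autofluorescence Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and statistical analysis of liver endogenous
    fluorescence (autofluorescence) spectra for grading diet-induced
    hepatic steatosis.  Provides a generative model of fluorophore-mixture
    emission spectra for control and methionine-choline-deficient (MCD)
    dietary groups, instrument-aware preprocessing (dark subtraction,
    spectral-sensitivity correction, boxcar smoothing, range restriction,
    single-wavelength normalization), spectral area-under-curve statistics
    with ANOVA/Tukey group comparisons and Spearman correlation against
    lipid content, and a classification chain of principal component
    reduction, Box's M covariance-homogeneity gate, quadratic discriminant
    analysis with leave-one-out cross-validation, canonical score planes
    with gridded decision boundaries, and one-vs-rest ROC analysis with
    Youden-index optimal operating points.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
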