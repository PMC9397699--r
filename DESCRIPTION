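Package: chaolle
Title: Optimized Largest Lyapunov Exponent Features for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification for two-class motor-imagery
    EEG (open hand versus fist) based on the largest Lyapunov exponent (LLE) of
    band-limited epochs. Time-delay embedding parameters are selected by mutual
    information (lag) and false nearest neighbors (dimension); their search
    ceilings are treated as free parameters and tuned per class by Tug-of-War,
    Chaotic Tug-of-War and Intelligent Water Drop metaheuristics under a fixed
    evaluation budget. Features are classified with a soft-margin support vector
    machine using a generalized radial basis function kernel. Includes synthetic
    generators for canonical chaotic systems with known Lyapunov exponents and
    for two-class event-related desynchronization epochs, so the whole pipeline
    is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    kernlab,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Collate: 
    'RcppExports.R'
    'chaolle-package.R'
    'classes.R'
    'classify.R'
    'embedding.R'
    'lyapunov.R'
    'optimizers.R'
    'preprocess.R'
    'pipeline.R'
    'synthetic.R'
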