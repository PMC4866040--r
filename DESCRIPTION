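Package: varpsim
Title: Virtual-Heart Arrhythmia Risk Prediction on Synthetic Infarcted Tissue Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of infarct-related ventricular arrhythmia
    induction. Builds synthetic labeled cardiac tissue models (2D sheets, 3D
    slabs and idealized truncated-ellipsoid ventricles) with parameterized
    scar and grey-zone morphologies, classifies signal-intensity volumes into
    scar/grey-zone/normal tissue by the full-width-at-half-maximum rule,
    assigns rule-based fibre orientations via Laplace-Dirichlet fields and
    bidirectional spherical linear interpolation, solves the anisotropic
    monodomain reaction-diffusion equations with a human ventricular ionic
    model (including grey-zone electrophysiological remodelling), and runs a
    multi-site programmed electrical stimulation protocol (S1-S4 decremental
    extrastimuli from 19 biventricular endocardial sites) that classifies
    each model as arrhythmia-inducible or not and measures induced
    ventricular-tachycardia cycle lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'varpsim-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cell.R'
    'fem.R'
    'solver.R'
    'varp.R'
    'geometry.R'
    'benchmark.R'
    'fibers.R'
    'mesh-io.R'
    'segmentation.R'
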