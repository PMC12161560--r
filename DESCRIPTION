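Package: dsvae
Title: Disentangled Sequential Variational Autoencoders for Windowed
    Multivariate Timecourses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Factorizes windowed multivariate timecourses (for example ICA
    component timecourses from resting-state fMRI) into slowly varying
    window-level context embeddings and fast timestep-level local embeddings
    with sequential variational autoencoders, in dependent (DSVAE) and
    independent (IDSVAE) form, alongside local-only and context-only
    baselines and a windowed functional network connectivity (wFNC)
    pipeline.  Includes seeded training with grid search, an evaluation
    suite (window classification, cross-seed reliability, embedding-space
    versus connectivity-space manifold comparison, patient clustering with
    dwell-time statistics and cluster connectivity maps), and a synthetic
    cohort generator with known slow/fast latent structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io_windows.R'
    'synthetic.R'
    'models.R'
    'training.R'
    'wfnc.R'
    'evaluation.R'
    'pipeline.R'
RoxygenNote: 7.3.3
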