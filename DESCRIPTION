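Package: latentmave
Title: Latent Phenotype Models for Multiplex Assays of Variant Effect
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers quantitative genotype-phenotype maps jointly with
    nonlinear, noisy measurement processes from multiplex assays of
    variant effect (MAVEs), including deep mutational scanning and
    massively parallel reporter or splicing assays. Sequences are mapped
    to a one-dimensional latent phenotype by additive, neighbor,
    pairwise, multilayer-perceptron or custom (e.g. thermodynamic)
    genotype-phenotype maps; measurements are modelled either by global
    epistasis regression (monotonic sum-of-sigmoids nonlinearity with
    Gaussian, Cauchy, skewed-t or empirical noise) or by a
    measurement-process-agnostic softmax model for binned readouts.
    Models are fit by regularized maximum likelihood, identifiability is
    restored by diffeomorphic and hierarchical gauge fixing, and model
    performance is assessed with variational, predictive and intrinsic
    information estimated via k-nearest-neighbor and
    Kraskov-Stogbauer-Grassberger estimators, with subsampling
    uncertainties and parametric-bootstrap parameter errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'alphabets.R'
    'encoding.R'
    'dataset.R'
    'scores.R'
    'gpmap-classes.R'
    'gpmap-blackbox.R'
    'gpmap-custom.R'
    'gauge.R'
    'noise-models.R'
    'ge-measurement.R'
    'mpa-measurement.R'
    'latent-model.R'
    'likelihood.R'
    'fit.R'
    'info-metrics.R'
    'simulate.R'
    'bootstrap.R'
    'biophysics.R'
    'serialize.R'
    'zzz.R'
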