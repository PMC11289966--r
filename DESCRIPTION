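Package: slnatlas
Title: Breast Sentinel Lymph Node Drainage Statistics and Target Volume Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical and geometric analysis of breast sentinel lymph node
    (SLN) mapping cohorts derived from lymphoscintigraphy and SPECT/CT.
    Estimates lymphatic drainage probabilities per node field and tumour
    prevalence per clockface breast region with three interval methods each:
    exact conjugate Bayesian posteriors (uniform Beta / flat Dirichlet priors),
    patient-level non-parametric bootstrap, and logit-scale Wald or Sison-Glaz
    simultaneous intervals. Also scores SLN coverage by radiotherapy clinical
    target volumes (5 mm spheres against voxel labelmaps), computes
    landmark-based registration-error metrics, and ships a synthetic
    cohort/geometry generator so the full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
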