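Package: seegplan
Title: Vascular-Model Fidelity in Stereotactic Electrode Trajectory Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic-phantom study of how vascular imaging fidelity affects
    computer-assisted stereoelectroencephalography (SEEG) trajectory planning.
    Generates seeded head phantoms with branching vascular trees rendered at
    three modality fidelities, segments vessel models (multiscale Hessian
    vesselness, isosurface extraction, centerline radius estimation, diameter
    pruning), co-registers modalities by normalized mutual information, plans
    multi-electrode implantations with a cumulative risk score, and quantifies
    apparent versus true risk across models together with the paired
    nonparametric statistics of the comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
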