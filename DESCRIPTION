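Package: fetalicv
Title: Automatic Fetal Intracranial Volume from 3D Ultrasound by Atlas Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures fetal intracranial volume (ICV) from 3D ultrasound
    volumes by registering an average brain model (atlas) to each subject
    scan through a staged linear plus B-spline free-form deformation
    pipeline, propagating the model's ICV mask through the inverse of the
    final transformation, and validating every measurement with a
    dual-pipeline consensus quality-control scheme (standard-deviation gate
    plus an overlap-similarity floor). Includes groupwise average-template
    construction, a seeded synthetic head-phantom generator with exact
    ground-truth ICV for end-to-end validation, and a command-line
    interface for preprocessing, model building, measurement and QC
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
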