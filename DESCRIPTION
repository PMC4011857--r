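Package: fissint
Title: Pulmonary Fissure Integrity Quantification from Thoracic CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects pulmonary fissures in thoracic CT-like volumes with a
    Hessian plate-likeness filter, labels them anatomically (right oblique,
    right horizontal, left oblique), extrapolates each detected fissure to
    the complete inter-lobar boundary with a thin-plate spline, and reports
    fissure integrity as the percentage of the boundary area on which the
    fissure is depicted. Includes a synthetic thoracic phantom generator
    with known ground truth, a paired spirometry simulator spanning
    non-COPD through GOLD-IV, and cohort-level statistics (GOLD staging,
    integrity-level distribution tables, Pearson and Spearman correlation
    with lung function and disease severity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
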