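Package: rvlvcad
Title: Automated Axial Right-Ventricle to Left-Ventricle Diameter Ratio
    from CT Pulmonary Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully automated measurement pipeline for the axial RV/LV
    diameter ratio, the CT prognostic biomarker of right-heart strain in
    acute pulmonary embolism. Ventricles are detected per axial slice with
    a sliding-window classifier, linked across slices by mean-shift
    clustering, the interventricular septum is estimated as a 3D plane
    from second-order image derivatives, both chambers are segmented with
    a seeded 3D level set constrained by the septum, and per-slice
    diameter calipers perpendicular to the septum yield the ratio after
    polynomial contour analysis excludes the atria. Includes a synthetic
    cardiac CT phantom generator with analytic ground truth for
    end-to-end validation, and readers/writers for NIfTI, MetaImage and
    single-frame CT DICOM series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
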