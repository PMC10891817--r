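Package: fidreg
Title: Landmark-Based Rigid Registration for Multimodal Valve Assessment and
    Jaw Mirror Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fiducial (landmark) rigid registration of 3D/4D medical
    image volumes, built around two workflows: fusion of ECG-gated cardiac CT
    with free-running 4D transesophageal ultrasound for mitral-valve
    assessment (temporal phase matching, resampling and centering, closed-form
    rigid landmark registration, FRE/RMSE error metrics, and a landmark-count
    reproducibility study), and unilateral jaw reconstruction by sagittal
    mirroring with local landmark registration and re-segmentation. Includes
    NRRD and NIfTI volume I/O in a consistent LPS convention, Slicer-style
    fiducial file formats, and synthetic 4D cardiac and jaw phantoms with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
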