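Package: quo2calib
Title: Calibrated BOLD fMRI Mapping of M, OEF and CMRO2 from Combined
    Hypercapnia and Hyperoxia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-calibrated (hypercapnia + hyperoxia)
    functional MRI. Converts continuous respiratory O2/CO2 traces into
    corrected end-tidal epoch summaries, models blood oxygen carriage
    (Severinghaus saturation, arterial O2 content, venous deoxyhemoglobin
    ratio, PaO2-dependent arterial blood T1), quantifies CBF from dual-echo
    pCASL with a slice-wise hyperoxia blood-T1 correction, and solves the
    generalized calibration model voxelwise for the maximum-BOLD parameter M,
    resting oxygen extraction fraction and absolute resting CMRO2. Includes an
    O2-level sensitivity sweep, test-retest repeatability statistics (dSD,
    wsSD, wsCV, bsCV, scale decision, Holm-corrected ROI comparisons) and a
    forward simulator that generates gas traces, voxelwise responses and 4D
    dual-echo ASL series from known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
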