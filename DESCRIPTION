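Package: wbdwi
Title: Whole-Body Diffusion-Weighted MRI Tumor Burden and ADC Histogram Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Semi-automatic segmentation of metastatic bone disease on
    whole-body diffusion-weighted MRI (WBDWI). Fuses multi-station
    acquisitions with per-station gain and phase-encode shift correction,
    computes apparent diffusion coefficient (ADC) maps and extrapolated
    high-b-value images (computed DWI), segments disease by thresholding
    with GrowCut editing and Markov random field smoothing, and derives
    total diffusion volume (tDV) and global ADC (gADC) histogram metrics
    for treatment-response assessment. Includes a synthetic multi-station
    phantom generator with ground truth so the full pipeline is testable
    without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
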