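Package: maldiscreen
Title: MALDI MS Profiling of Fingermark Tryptic Digests for Breast Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a fingertip-smear MALDI MS profiling
    analysis for non-invasive breast cancer screening. Provides in silico
    tryptic digestion of a spacer-linked master protein sequence with missed
    cleavages and methionine oxidation, peptide mass fingerprint matching under
    ppm tolerances with blank screening and contaminant exclusion, the spectral
    preprocessing chain (Savitzky-Golay smoothing, thresholded peak detection,
    centroiding, charge-1 deisotoping), featurization of peak lists into a
    dense samples-by-m/z matrix by 1-decimal-place rounding, four from-scratch
    supervised learners (KNN, C4.5-style decision tree, SMO-trained polynomial
    SVM, single-hidden-layer MLP) and donor-grouped stratified tenfold
    cross-validation with pooled out-of-sample confusion matrices. A synthetic
    cohort generator emulates the study design (15 donors, 3 classes, 135
    spectra) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
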