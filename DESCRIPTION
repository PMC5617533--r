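Package: ohsccmpi
Title: Multiparametric PET/MRI Prognostic Modelling for Advanced Pharyngeal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for multiparametric imaging prognostics in advanced
    oropharyngeal and hypopharyngeal squamous cell carcinoma. Computes
    conventional FDG-PET metabolic parameters (SUVmax, SUVmean, MTV, TLG)
    under fixed and adaptive SUV-threshold segmentation, intratumoural
    heterogeneity features from the 13-direction three-dimensional
    normalized gray-level co-occurrence matrix (NGLCM) and the neighborhood
    gray-tone difference matrix (NGTDM) at 32 and 64 gray levels,
    extended Tofts-Kety pharmacokinetic parameters from DCE-MRI with
    variable-flip-angle T1 mapping, and apparent diffusion coefficients
    from two-b-value DWI. Survival tooling covers Kaplan-Meier estimation,
    log-rank based optimal dichotomization cutoffs, Cox regression, and a
    composite 0-4 risk-factor prognostic score with stratified reporting.
    A synthetic-data module generates PET phantoms, DCE/DWI series, and
    survival cohorts with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    minpack.lm,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
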