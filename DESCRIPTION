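Package: lungqmri
Title: Quantitative Lung MRI Analysis on a Digital Phantom: TE-Dependent T1
    Mapping and DCE Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a digital lung phantom with known ground truth and
    quantifies it the way a morpho-functional lung MRI study would: per-voxel
    T1 fitting of inversion-recovery ultra-short-echo-time series at several
    echo times, perfusion quantification from dynamic contrast-enhanced
    series (arterial input function detection, truncated-SVD deconvolution,
    pulmonary blood flow, Otsu two-threshold perfusion-defect classification
    and the defect percentage QDP), registration-based and registration-free
    equal-volume-subdivision spatial correspondence, and the inter-patient
    and local Spearman/Wilcoxon statistics that relate T1(TE) to perfusion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
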