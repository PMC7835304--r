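Package: petspio
Title: Multimodal PET and SPIO-MRI Quantification of Neuroinflammation in
    Mouse EAE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for combined TSPO-PET and iron-oxide
    (SPIO) T2*-weighted MRI studies of microglial activation and macrophage
    infiltration in mouse experimental autoimmune encephalomyelitis (EAE).
    Provides landmark-based rigid and affine co-registration with volume
    resampling, standardized uptake value (SUV) and reference-region SUV
    ratio (SUVR) quantification of dynamic PET over atlas volumes of
    interest, polynomial bias-field correction, automated brain extraction
    and histogram-threshold labelling of hypointense SPIO uptake sites with
    per-region fractional volumes (SPIO-Vol), fluorescence co-localization
    and perivascular co-expression statistics, nonparametric group
    comparison and rank-correlation reporting, and a seedable synthetic
    phantom cohort generator with recorded ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
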