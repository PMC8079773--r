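Package: radiogbm
Title: Radiomic Outcome Modelling for Recurrent Glioblastoma MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomic analysis pipeline for gadolinium-enhanced T1-weighted MR
    imaging of recurrent glioblastoma. Provides MR intensity normalization
    (fixed bin number and two-point linear rescaling against white-matter and
    vitreous-body reference tissues), tumoral and peritumoral (15-mm rim)
    volume-of-interest construction, extraction of 180 IBSI-style shape,
    intensity and texture features (GLCM, GLRLM, GLSZM, GLDZM, NGTDM, NGLDM),
    feature grouping by principal component analysis with Horn's parallel
    analysis, univariable screening, multivariable logistic and Cox models
    with AIC backward selection, external-cohort validation, 5-fold cross
    validation, median-threshold risk stratification with log-rank testing,
    and MR image-quality auditing. A synthetic phantom and cohort generator
    with known ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    survival,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
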