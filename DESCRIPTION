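Package: synovkit
Title: Quantification and Discrimination of Synovial Inflammation in
    Osteoarthritis and Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for discriminating osteoarthritis (OA) from rheumatoid
    arthritis (RA) synovium on hematoxylin-and-eosin stained tissue. Provides a
    classical computer-vision quantifier of nuclei density (cells per mm^2 of
    tissue) built on tile decomposition, Otsu and local adaptive thresholding,
    watershed splitting and shape filtering; a canonical data model and CSV
    dialect for fourteen pathologist-scored semi-quantitative synovial
    histology features; a statistical discrimination engine (tie-aware
    Mann-Whitney ROC/AUC on ordinal scores, Youden J optimal cut-points,
    chi-square group comparisons, covariate-adjusted logistic regression, and
    a nested cross-validated random-forest classifier with fold-averaged and
    concatenated AUC summaries); and a synthetic-data module that generates
    ground-truthed H&E-like image tiles and OA/RA cohorts with known marginal
    and dependence structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
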