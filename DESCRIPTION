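Package: voctrait
Title: Linking Fungal Volatilomes to Taxonomy and Ecological Guild
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fungal volatile organic compound (VOC)
    emission profiles measured on two platforms (PTR-ToF-MS mass features
    and GC-MS annotated compounds): feature-table preprocessing (reagent-ion
    normalisation, spline background subtraction, Kovats retention indices,
    isotopologue and fragment handling), chemical-diversity summaries
    (Pielou evenness), Spearman-correlation compound clustering,
    cross-validated discriminant analysis of principal components (DAPC)
    chemotyping, a phenotypic-integration index (eigenvalue variance of the
    compound correlation matrix) with permutation null calibration, and a
    three-model consensus machine-learning procedure for volatile biomarker
    discovery. Includes a synthetic dual-platform volatilome generator with
    planted guild structure and biomarkers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    randomForest,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust
Config/testthat/edition: 3
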