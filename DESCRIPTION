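Package: petromics
Title: Metabolic Radiogenomics of FDG PET Tumor Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for metabolic radiogenomics in lung cancer:
    gradient-based tumor delineation on SUV-scaled PET volumes, an
    86-feature intensity/texture catalog (GLCM, GLRM, GLSZM, NGLD and
    texture-feature-coding families), empirical-Bayes batch harmonization
    across scanners, screening of feature-by-gene-alteration associations
    with a rescaled fold-change statistic and Benjamini-Hochberg false
    discovery control, consensus clustering of patients with
    proportion-of-ambiguous-clustering model selection, oncogenic-pathway
    aggregation of variant calls, and Kaplan-Meier/Cox survival
    stratification. Ships synthetic phantom and cohort generators with
    known ground truth so every stage is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    RNifti,
    survival,
    sva,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
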