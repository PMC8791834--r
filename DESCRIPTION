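Package: neopredict
Title: Multi-Omic Prediction of Response to Neoadjuvant Breast Cancer Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives DNA, RNA and digital-pathology features of pre-treatment
    breast tumours (cancer cell fraction and clonality, tumour mutation burden,
    mutational signature exposures, HRD scar scores, HLA loss of heterozygosity
    and neoantigen filtering, TMM/TPM normalization, single-sample gene-set
    enrichment, immune metagenes, nearest-neighbour cell densities), tests their
    association with ordinal residual cancer burden, and trains a seed-averaged
    ensemble classifier (elastic-net logistic regression, support vector machine,
    random forest) to predict pathological complete response. Includes a fully
    synthetic multi-omic cohort generator with known ground truth so the entire
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    edgeR,
    glmnet,
    e1071,
    randomForest,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
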