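Package: PatientSimRec
Title: Multidimensional Patient-Similarity Therapy Recommendation for Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for similarity-based medication-plan recommendation in heart
    failure from tabular EHR-style extracts. Builds a response-labeled cohort by
    ejection-fraction phenotyping (ICD-9 428.x diagnosis, index EF < 50%,
    follow-up EF window, exclusion diagnoses), encodes patients as numeric
    feature vectors, clusters good responders by supervised (plan-defined),
    k-means and Ward hierarchical strategies with a 5% small-cluster merging
    rule based on plan-set Jaccard similarity, and recommends the medication
    plan of the nearest cluster under a generalized Mahalanobis distance with a
    symmetric positive semi-definite metric. Includes a seeded synthetic cohort
    generator with plantable latent structure for end-to-end validation, and a
    repeated stratified split evaluation protocol (specificity, sensitivity,
    F1, accuracy, AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PatientSimRec-package.R'
    'cluster.R'
    'cohort.R'
    'evaluate.R'
    'features.R'
    'generator.R'
    'similarity.R'
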