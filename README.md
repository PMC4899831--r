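# PatientSimRec

Multidimensional patient-similarity analytics for heart-failure therapy
recommendation.

## What problem this solves

Clinicians choosing a heart-failure (HF) medication plan can, in principle,
learn from previously treated patients who resembled the new patient and
responded well. PatientSimRec implements that idea as a reproducible
pipeline over tabular EHR-style extracts (patients, EF measurements,
diagnoses, medications):

1. **Cohort phenotyping** — four eligibility criteria (ICD-9 428.x HF
   diagnosis; an index ejection fraction < 50% within 30 days of diagnosis;
   a follow-up EF 180–450 days later; no prior exclusion diagnosis), then
   good/poor response labeling: *good* means the EF rose by at least 10
   points within 12 months of treatment initiation.
2. **Feature encoding** — each patient becomes a numeric vector
   `x ∈ R^d` (labs, vitals, age, index EF z-scored; demographics one-hot;
   26 CCW comorbidity flags). The medication plan — a nonempty subset of
   {ACEI, ARB, BB, CCB, Statin} — is the class label, never a feature.
3. **Clustering of good responders** — k-means (seeded k-means++),
   Ward hierarchical, or supervised (one cluster per plan), each cluster
   labeled with its modal plan; small clusters (< 5% of the clustered
   population) are absorbed into the large cluster with the most similar
   plan (Jaccard of drug-class sets, superset-preferring tie-break).
4. **Recommendation** — the generalized Mahalanobis distance

   `d_S(x, C) = sqrt((x − μ)ᵀ S (x − μ))`,

   with S symmetric positive semi-definite (identity, or the pseudo-inverse
   of the shrunk pooled within-cluster covariance), ranks clusters; the
   nearest cluster's plan is recommended.
5. **Evaluation** — repeated seeded stratified 70/30 splits; specificity,
   sensitivity, F1, accuracy and AUC of the plan-match-among-responders
   outcome, with the AUC computed on the exact empirical ROC (equal to the
   Mann–Whitney statistic).

Because cohorts of this shape are not publicly available, the package
includes a seeded synthetic generator calibrated to the characteristics of
a reference HF cohort (n = 1386, 57% good responders, ACEI+BB+Statin the
modal plan at 17%), with a *plantable* latent phenotype structure that gives
every stage a testable ground truth.

## Worked example

```r
library(PatientSimRec)

# a synthetic study-sized cohort with planted structure
cfg <- defaultGeneratorConfig(nPatients = 1386, seed = 1,
                              groupSeparation = 8, planMatchEffect = 0.5)
sc    <- generateCohort(cfg)
built <- buildCohort(cohortExtracts(sc))
nrow(built$cohort)                 # 1248 eligible patients
table(built$cohort$response)       # good 687 / poor 561

ev <- evaluateMethods(built$cohort,
                      methods = c("supervised", "hierarchical", "kmeans"),
                      k = 4, nRuns = 5, seed = 1)
ev$summary[, c("method", "specificity", "sensitivity", "f1", "accuracy", "auc")]
#>         method specificity sensitivity    f1 accuracy   auc
#> 1   supervised       0.953           1 0.929    0.964 0.948
#> 2 hierarchical       0.952           1 0.941    0.965 0.960
#> 3       kmeans       0.952           1 0.941    0.965 0.960
```

Reading the output: 1386 simulated patients yield 1248 eligible ones (the
generator plants ~10% eligibility failures); 687 (55%) respond. Each
evaluation run clusters the training good responders, recommends a plan for
every held-out patient by nearest cluster, and scores the recommendation
against the observed plan and response. On this planted cohort (latent
groups 8 SDs apart, plan-match response uplift 0.5) the recommender
recovers the planted plan–phenotype linkage: AUC ≈ 0.95 for all three
strategies. Sensitivity is structurally 1 under the plan-match outcome
coupling (see the methods vignette); specificity, F1, accuracy and AUC are
the informative columns. With `planMatchEffect = 0` the same pipeline
returns AUC ≈ 0.5 — the package's own null check.

A command-line front end covering the same steps
(`simulate`, `build-cohort`, `train`, `evaluate`) is installed at
`inst/scripts/simrec.R`.

## Layout

```
R/                      S4 classes, generator, cohort builder, encoder,
                        cluster engine, similarity recommender, evaluation
tests/testthat/         unit, property and acceptance tests (all synthetic,
                        generated in code)
scripts/acceptance.R    end-to-end reproduction script
inst/scripts/simrec.R   command-line interface
vignettes/              methods vignette (model, parameters, design choices)
```
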