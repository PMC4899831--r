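---
title: "Similarity-based therapy recommendation for heart failure: methods and design"
author: "PatientSimRec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based therapy recommendation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatientSimRec)
```

## The problem

Heart-failure (HF) patients differ widely in how they respond to drug
therapy. Given an EHR-derived cohort in which each patient has a measured
response — an ejection-fraction (EF) trajectory after treatment initiation —
and a medication plan (a subset of the five drug classes ACEI, ARB,
beta-blocker, statin, CCB), the question is whether a *new* patient's plan
can be chosen by looking at which previously-treated, *good-responding*
patients they resemble. PatientSimRec implements that pipeline end to end:
cohort phenotyping, feature encoding, clustering of good responders,
nearest-cluster recommendation under a generalized Mahalanobis distance, and
a repeated-split evaluation protocol. Because real clinical extracts of this
kind are not publicly available, the package ships a calibrated synthetic
cohort generator with a *plantable* latent structure, so every stage can be
validated against a known ground truth.

## Cohort phenotyping

Four eligibility criteria define the analysis cohort:

1. an HF diagnosis (ICD-9-CM prefix 428);
2. an EF measurement below 50% within 30 days of the earliest HF diagnosis
   (the earliest such measurement is the *index EF*);
3. another EF measurement 180–450 days (6–15 months) after the index EF
   (the earliest in-window measurement is the *follow-up EF*);
4. no exclusion diagnosis (coronary artery disease, myocarditis,
   cardiomyopathy, aortic or mitral stenosis) strictly *before* the HF
   diagnosis; a same-day code does not count as prior.

Patients missing any modeling feature are excluded as incomplete cases, and
malformed records are collected into a validation report rather than
silently dropped. A criterion whose anchor is missing (no HF diagnosis, no
index EF) is treated as indeterminate rather than failed, so each excluded
patient carries the *first* decidable reason.

Response is labeled from the EF trajectory: **good** means the follow-up EF
exceeds the index EF by at least 10 EF percentage points with the follow-up
within 365 days of treatment initiation, otherwise **poor**. Three choices
here are deliberately configurable because the underlying definitions are
ambiguous in routine clinical text:

* "10% increase" is read as 10 *absolute* EF points (the scale EF is
  reported on); `eligibilityWindows(relativeResponse = TRUE)` switches to a
  relative 10% gain.
* All windows are day counts (30 / 180–450 / 365), never calendar months,
  for determinism.
* Treatment initiation defaults to the index EF date;
  `initiationFromMedication = TRUE` uses the earliest medication start.
* The exclusion ICD-9 prefix list (414, 422, 429.0, 425, 424.1, 394.0, 396)
  is an editorial default — no canonical code list exists for the named
  conditions — and is a named argument.

## Feature encoding

Each patient is encoded as \(x_i \in \mathbb{R}^d\) in a fixed canonical
order: 8 continuous features (age, BMI, systolic blood pressure, hemoglobin,
sodium, cholesterol, lymphocytes, index EF), z-scored with constants fitted
on *training patients only*; one-hot indicators for sex, race and ethnicity
(first level alphabetically is the reference); and 26 binary flags for the
CCW chronic conditions, giving \(d = 37\) by default. Unseen categorical
levels at encoding time are an error, never a silent zero.

Medication classes are deliberately **not** features: the plan is the class
label the recommender predicts, and including it in \(x_i\) would leak the
label. `fitSchema(includeMedications = TRUE)` exists for replication
experiments only. Z-scoring is chosen so that the identity-metric distance
degrades gracefully to a scale-free Euclidean distance.

## Clustering good responders

Only good responders are clustered — the point of the method is to find
*which kind of patient responded to which plan*; poor responders enter
evaluation only. Three strategies are provided:

* **kmeans** — Lloyd's algorithm with seeded k-means++ initialization and
  10 restarts (best total within-cluster sum of squares kept), `k = 7` by
  default;
* **hierarchical** — Ward (`ward.D2`) agglomeration on Euclidean distances,
  cut at `k`;
* **supervised** — one cluster per distinct canonical plan (plan-pure by
  construction).

Unsupervised clusters are labeled with the modal member plan; ties break by
the plan's whole-training-set frequency, then by the lexicographically
smallest canonical string.

### The 5% merging rule

Supervised clustering typically yields dozens of small clusters. A cluster
holding less than 5% of the clustered population is absorbed into the large
cluster whose label plan is most similar, where similarity is the **Jaccard
index of the drug-class sets**. This choice reproduces the intended
"superset absorption" behaviour: a small \{statin, CCB, ACEI\} cluster joins
\{statin, CCB, ACEI, BB\} (Jaccard 3/4) rather than a less-overlapping large
plan. Ties prefer a strict superset plan, then the largest cluster, then
lexicographic order; if no cluster meets the threshold the smallest cluster
merges into its best-Jaccard peer, so the procedure never fails. Every step
is recorded in a merge log; membership is conserved; the count strictly
decreases so at most \(k - 1\) merges occur. The denominator of the 5% rule
is the clustered (good-responder training) population — the population the
rule is applied to. By default merging applies to supervised results only
(`mergeUnsupervised = TRUE` extends it).

## The similarity metric and recommendation

The distance between a patient \(x\) and a cluster with centroid \(\mu\) is

\[ d_S(x, C) = \sqrt{(x - \mu)^\top S (x - \mu)}, \]

with \(S\) symmetric positive semi-definite (SPSD; validity enforces
symmetry to \(10^{-10}\) and smallest eigenvalue above \(-10^{-8}\)).
The choice of \(S\) is the method's main degree of freedom, and the package
offers three provenances:

* `identity` — Euclidean distance in the z-scored space;
* `pooled_inverse_covariance` (default) — Moore–Penrose pseudo-inverse of
  the shrunk pooled within-cluster covariance
  \((1-\lambda)\hat\Sigma + \lambda\,\mathrm{diag}(\hat\Sigma)\), with
  \(\lambda = 0.1\); shrinkage keeps the estimate invertible-ish at
  \(n\) close to \(d\), and the pseudo-inverse covers the rest. With fewer
  than \(d + 1\) training points the identity is used with a warning;
* `per_cluster_inverse_covariance` — offered for exploration but flagged:
  distances under per-cluster metrics are not comparable as a single metric.

Two numerical conventions matter. First, the square root is applied (the
classical Mahalanobis form); since \(\sqrt{\cdot}\) is monotone, rankings —
and therefore every recommendation — are identical with or without it, a
property the tests check explicitly. Second, quadratic forms that come out
slightly negative from floating-point error (above \(-10^{-10}\)) are
clamped to zero; anything lower raises an SPSD-violation error.

Recommendation ranks all clusters by ascending distance and returns the
nearest cluster's label plan, with a deterministic tie-break (larger
cluster, then lexicographically smaller plan) so runs are reproducible. The
margin (runner-up minus winner) is reported, `NA` when only one cluster
exists.

## Evaluation protocol

`evaluateMethods()` performs `nRuns = 10` independent seeded **stratified
70/30 splits** (stratified on response; largest-remainder allocation makes
the train size exactly `round(0.7 n)` — a 1386-patient cohort always splits
970/416). Literal k-fold cross-validation is not used: repeated 70/30
splits with averaged metrics match the stated design of one training share
and one test share per run.

Per test patient the **outcome** is 1 iff the patient was a good responder
*and* the recommended plan equals the observed plan (canonical string
equality); the **score** is the negated distance to the winning cluster;
the **prediction** is the plan match itself. Specificity, sensitivity, F1
and accuracy come from the prediction/outcome confusion matrix. Note a
structural consequence of this coupling: a positive outcome implies a
positive prediction, so false negatives are impossible and sensitivity is
identically 1; specificity, F1, accuracy and AUC are the informative
quantities. The positive-class definition determines all five metrics and
is therefore stated prominently here.

The AUC integrates the exact empirical ROC over *all* distinct score values
(trapezoidal rule with tie segments), which equals the Mann–Whitney
formulation to machine precision — the package computes both and the tests
require agreement below \(10^{-9}\). The configured cut points (score
percentiles, ascending from the 50th) define the *reported* ROC operating
points; a coarse-grid trapezoid would systematically underestimate the AUC,
so cut points are presentation, not the AUC's resolution.

`planFrequencyByEF()` summarises the top plans within half-open index-EF
bins \([0,10), [10,20), \ldots, [40,50)\).

## The synthetic cohort generator

`defaultGeneratorConfig()` encodes the study conditions: continuous
marginals (age 77±13, BMI 28.4±10.8, systolic BP 121±23, hemoglobin 13±1.9,
sodium 140±6.9, cholesterol 155±42, lymphocytes 1.53±0.78, baseline EF
37±9.8 truncated below 50), 65% male, 96% White, 90% non-Hispanic, 26 CCW
comorbidity prevalences, a 57% good-responder rate, and plan frequencies
assigning 0.17 to ACEI+BB+Statin and 0.12 to ACEI+BB with the remaining
mass uniform over the other 29 nonempty plans. Four of the 26 CCW
conditions (related dementia, endometrial cancer, hip/pelvic fracture, lung
cancer) and anemia have no reference prevalence in the calibration targets;
their defaults (0.30, 0.006, 0.05, 0.025, 0.50) are editorial and
overridable, as are the sex/ethnicity percentages.

Two design points deserve emphasis:

* **Moment-matched truncation.** Continuous variables are truncated normals
  whose *underlying* parameters are solved numerically so the *truncated*
  distribution attains the configured mean and SD. This matters for EF,
  which eligibility hard-caps below 50%: naive truncation would bias its
  sample mean down by almost 2 points. Calibration is checked at
  \(n = 5000\), where every configured marginal must sit within 3 standard
  errors of its target.
* **A plantable latent structure.** Each patient draws a plan from the
  configured frequencies (so plan marginals are exact), belongs to the
  plan's latent phenotype group with probability `planGroupCoupling` (0.9)
  when the plan is one of the `nLatentGroups` (4) preferred plans, and
  responds with probability \(p_0 + e\cdot[\text{plan matches the group's
  preferred plan}]\), where \(e\) is `planMatchEffect` and \(p_0\) is set so
  the marginal responder rate is exactly the configured 57%. Group
  centroids sit `groupSeparation` SDs apart in the continuous feature
  space; among many seeded orthonormal direction sets the generator keeps
  the one that stays most evenly separated *after* z-scoring, because
  per-feature standardization otherwise warps the planted geometry.

The linkage between features and outcome is carried by *phenotype
typicality*: patients who are not archetypes — not both plan-matched and
good responders — have their continuous noise SD inflated by
\(1 + 0.5e\) and their comorbidity probabilities blended toward 0.5 by
\(\min(2e, 1)\). The clinical reading is that patients who respond to their
group's preferred therapy are the typical members of that phenotype. All
three linkage channels (response uplift, dispersion, blending) are scaled
by `planMatchEffect`, so `planMatchEffect = 0` severs *every*
feature–plan–outcome link: features then carry no outcome information and
the end-to-end AUC is 0.5 by construction, which the null-calibration test
verifies over 20 seeds. Defaults are `groupSeparation = 0` and
`planMatchEffect = 0` — the default cohort is a pure marginal replica with
no planted structure, because planting a separation necessarily inflates
the very marginal SDs the calibration targets fix. Planted-structure runs
(e.g. separation 8, effect 0.5) state those parameters explicitly.

A configured fraction (10%) of patients is planted to fail one eligibility
criterion each, cycling over the four criteria, so the cohort builder can
be checked decision-by-decision against ground truth.

**What the generator does not emulate:** inter-variable clinical
correlations (an optional correlation hook is out of scope; variables are
independent given the latent group), longitudinal EHR noise (coding errors,
censoring, irregular measurement), dosages, and ICD-10. Passing tests on
synthetic cohorts therefore demonstrate the *pipeline's* correctness and
its behaviour under a known feature–plan–response linkage — not clinical
performance on real EHR data.

## Problem sizes and seeds used by the test suite

The suite validates planted recovery on cohorts of \(n = 2000\) (4 groups,
separation 8 SD, effect 0.5), null calibration on 20 cohorts of
\(n = 2000\) with effect 0, and marginal calibration at \(n = 5000\) —
sizes at which binomial/normal standard errors make the stated tolerances
meaningful (3 SEs for marginals, ±0.02 for the responder rate, ±0.03 for
the null AUC mean). All stochastic steps take explicit integer seeds, and
equal seeds reproduce byte-identical extracts and evaluation reports.

## Known limitations

* The supervised strategy's merged clusters inherit the label of the
  absorbing plan; patients of rare plans are therefore evaluated against a
  coarser plan vocabulary.
* Per-cluster metrics break the single-metric interpretation of the
  ranking; they are provided for exploration with a warning.
* The recommendation outcome is retrospective plan-match among good
  responders, not a counterfactual claim that the recommended plan *would
  have* produced a response; a prospective reading cannot be evaluated
  from observational extracts of this shape.
* With 31 possible plans the binary match/mismatch reduction discards the
  structure of partial plan overlap in evaluation (the merge rule uses it;
  the metrics do not).
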