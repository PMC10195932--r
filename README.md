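# phenoprint

Temporal phenotype fingerprinting of prodromal clinical trajectories.

Many psychiatric disorders — bipolar disorder prototypically — are preceded
by a *prodrome*: months of early symptoms, abnormal labs and rising
healthcare contact before the first characteristic diagnosis. `phenoprint`
implements an unsupervised pipeline for discovering distinct prodromal
phenotypes in longitudinal EHR-style data and linking them to one-year
prognoses. It is aimed at biostatisticians and clinical informaticians who
want to run, extend or stress-test this class of temporal-image clustering
analysis without access to protected health records.

## The method

1. **Temporal images.** Each patient's year before diagnosis is encoded as an
   F × W matrix (default 84 features × 53 weeks, columns −52…0 with week 0 the
   index week). Most rows are binary presence flags (hospitalization,
   ICD-9 diagnosis groups, CPT procedure groups, keyword-matched symptom
   groups); lab and vital rows carry graded abnormality scores in [0,1]
   (0 at the population mean / normal range, saturating at 1 for extreme
   values).

2. **Temporal blurring.** Euclidean distance on raw images treats the same
   diagnosis at two different times as maximally dissimilar. Before
   clustering, each image A is blurred along the time axis with a
   max-Gaussian kernel:

   B(i, j) = max<sub>j−10 ≤ k ≤ j+10</sub> A(i, k) · e<sup>−(k−j)²/10</sup>

   so that clinically similar trajectories at slightly different times
   become close.

3. **Clustering.** K-means (Lloyd, seeded k-means++-style initialization,
   best of 10 restarts) on the flattened blurred images; the number of
   clusters is guided by an SSE scan over k = 2…20 and its "elbow area".
   Each cluster's **phenotype fingerprint** is the element-wise mean of its
   members' *original* (unblurred) images.

4. **Outcomes.** Clusters are compared on one-year mortality,
   hospitalization rate, number of hospitalizations, length of stay and
   psychosis, using chi-square / ANOVA tests plus the absolute standardized
   difference (ASD) versus a reference cluster:
   d = |p₁−p₂| / √((p₁(1−p₁)+p₂(1−p₂))/2) for proportions and
   d = |m₁−m₂| / √((s₁²+s₂²)/2) for means, with ASD ≥ 10% flagging a
   meaningful difference.

A synthetic-cohort generator (`generateCohort()`) plants configurable
prodromal archetypes — onset week, intensity trajectory, active feature
rows, outcome rates — so the entire pipeline can be validated end to end.

## Worked example

```r
library(phenoprint)

co  <- generateCohort(defaultArchetypes(100L), seed = 42L)
std <- fitStandardizers(co$events, defaultRegistry())
imgs <- encodeCohort(co$events, patients = co$patients,
                     standardizers = std)
bl   <- blurImages(imgs)
m    <- relabelByMass(kmeansFit(bl, k = 8, seed = 42L), bl)
m
#> ClusterModel: k = 8, n = 800, SSE = 5105.604
#> cluster
#>   1   2   3   4   5   6   7   8
#> 100 100 100 100 100 100 100 100

mclust::adjustedRandIndex(clusterAssignments(m)[names(co$true_labels)],
                          co$true_labels)
#> [1] 1
```

The eight planted archetypes are recovered exactly (adjusted Rand index 1);
`fingerprints(imgs, m)` returns the eight mean images and
`compareClusters(co$outcomes, m)` the outcome table, ASDs and tests. On the
published eight-cluster outcome statistics shipped with the package:

```r
ref <- referenceOutcomeStats()
asdPercent(asdBinary(ref$death_rate[ref$cluster == 6],
                     ref$death_rate[ref$cluster == 1]))
#> [1] 20
```

i.e. the cluster with a 4.6% one-year death rate differs from the 1.3%
reference cluster by a standardized 20% — well past the 10% threshold.

## Package layout

- `R/` — S4 classes (`FeatureRegistry`, `TemporalImageSet`, `ClusterModel`,
  `Fingerprint`) and the pipeline stages; `runPipeline()` orchestrates
  simulate → encode → blur → scan → cluster → fingerprints → outcomes with a
  checksummed manifest.
- `vignettes/fingerprinting.Rmd` — the methods vignette: model, parameter
  choices, generator design, numerical conventions, limitations.
- `inst/extdata/` — the default registry is built in code; the published
  cluster outcome statistics used for ASD validation live here as CSV.
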