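---
title: "Temporal phenotype fingerprinting: model, conventions and limitations"
author: "phenoprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal phenotype fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprint)
```

## The problem

Prodromal phases of psychiatric disorders leave a trace in routine
healthcare data: symptom mentions in notes, diagnosis and procedure codes,
abnormal labs and vitals, admissions. `phenoprint` asks whether patients
fall into *distinct* prodromal phenotypes in the year before their first
diagnosis, and whether those phenotypes carry different one-year prognoses.
Because the real data such analyses run on (national EHR warehouses) cannot
be redistributed, the package pairs the analysis pipeline with a
synthetic-cohort generator whose planted structure makes every stage
testable.

## Temporal images

Each patient is encoded as an F × W matrix: F = 84 feature rows, W = 53
weekly columns spanning weeks −52…0, week 0 being the week of the index
(first) diagnosis. Week binning is *toward zero*: an event d days before
the index lands in week `trunc(d/7)`, so the 7 days ending at the index
share week 0 and an event exactly 350 days prior is week −50. (A floor
convention would push an event 3 days before the index into week −1, which
contradicts the "index week" reading; the trunc convention is the one the
package commits to.)

The 84-row default registry is a documented convention, anchored by what
can be fixed externally — row 1 is hospitalization, rows 2–22 the
mental-disorder ICD-9 groups at three-digit detail, ascending chapter order
placing digestive diseases (520–579) at row 30, rows 61–84 the 24
bipolar-disorder symptom keyword groups — and filled in deterministically
elsewhere (seven CPT groups, the ten most frequent labs, five vitals).
Because the authoritative ordering of the remaining rows is not publicly
fixed, the registry is fully configurable: `loadRegistry()` accepts any
row count with an explicit override, and images simply follow the
registry's dimensions. Row identity does not affect the clustering
mathematics, only interpretation of fingerprints.

### Graded scores

Labs use a linear-in-|z| map with saturation:
score = min(|x − μ| / (c·σ), 1) with c = 3 by default, μ and σ fitted from
the cohort's own value distribution (`fitStandardizers()`). The published
description of this scoring fixes only the endpoints (0 at the population
mean, approaching 1 far from it); linear-in-z with a 3σ cap is the simplest
monotone map honouring both, and c is exposed as a parameter. Vitals use
per-side linear interpolation between a normal range (score 0) and extreme
bounds (score 1); the shipped bounds are clinically conventional adult
values and fully overridable through the registry metadata.

Same-week duplicates aggregate by maximum (graded) or logical OR (binary):
pixels mean "worst abnormality / any presence that week", which makes
encoding order-invariant and monotone under added events. Hospitalizations
mark every week overlapped by the admission–discharge interval, not just
the admission week.

Symptom flags are bare keyword presence (case-insensitive, word-boundary)
against an instrument-derived lexicon. There is no negation or context
handling — "denies insomnia" flags insomnia. This mirrors the simplicity of
the keyword rule the method was defined with and is a known limitation.

## Temporal blurring

The only nonstandard transform is the max-Gaussian temporal blur

$$B(i,j) = \max_{j-h \le k \le j+h} A(i,k)\, e^{-(k-j)^2/\delta},
\qquad h = 10,\ \delta = 10.$$

Its purpose: after blurring, two patients with the same feature at nearby
times are *close* in Euclidean distance, with closeness decaying in the
time gap, while unrelated features remain orthogonal. The formula is
implemented literally (δ is not interpreted as 2σ²); both h and δ are
parameters defaulting to the published values. The window is truncated at
the matrix edges — no padding — which preserves the dominance property
B ≥ A (the k = j term) and range preservation in [0,1]. The vectorized
implementation is shift-and-max over ±h column offsets and is verified to
1e−12 against an explicit triple-loop oracle (`blurOracle()`).

## Clustering

K-means with Euclidean distance on the row-major flattened blurred images,
all pixels equally weighted. Numerical choices:

* **Initialization.** Seeded k-means++-style spreading initialization with
  10 independent restarts, best SSE kept. This matters: with plain random-
  sample starts the default validation cohort converges to a partition with
  SSE ≈ 6364 that merges the two least-burdened archetypes, while the
  planted partition (SSE ≈ 5106) is a Lloyd fixed point — a pure
  initialization failure that spreading starts avoid.
* **Lloyd iterations** via `stats::kmeans` (max 300, convergence when
  assignments stabilise), empty-restart failures discarded.
* **Exact dimension reduction.** When D > N the points are rotated onto an
  orthonormal SVD basis of the cloud first; Euclidean distances and SSE are
  unchanged (rotation), Lloyd just runs on ≤ N coordinates. Centroids are
  rotated back.
* **Determinism.** Everything is reproducible given (data, k, seed,
  restarts); `sseScan()` uses seed + k per fit so each k is independently
  reproducible.
* **Label convention.** K-means labels are arbitrary, so `relabelByMass()`
  orders clusters by ascending mean total blurred pixel mass. Cluster 1 is
  then the least-burdened ("no prodrome") group and the natural outcome
  reference.

The number of clusters is a judgment call informed by the SSE scan:
`suggestElbow()` brackets the k of maximum discrete curvature (second
difference) of the SSE curve and returns `c(k−1, k+1)`; a flat or linear
curve returns the full range with a warning. The suggestion is advisory —
in the motivating analysis the curve had an elbow *area* (6–10) rather than
a point, and k = 8 was chosen on clinical interpretability.

Fingerprints are means of the **original**, unblurred images: blurring is a
distance device, not a representation of the phenotype. Two exact
identities are enforced in tests: fingerprint pixels stay within the member
pixel range, and the size-weighted mean of all fingerprints equals the
cohort mean image to 1e−12.

## Outcomes and standardized differences

Per cluster: one-year death rate, hospitalization rate, mean (sample SD)
hospitalization count and total length of stay, psychosis rate, the
proportion of hospitalization events due to mental illness, and the
proportion of hospitalized patients with ≥ 1 mental-illness admission.
Sample SDs are used throughout. Between-cluster significance uses
chi-square (binary) and one-way ANOVA (continuous — applied to skewed
counts and stays without transformation, deliberately matching the
published analysis). Because large cohorts make trivial differences
significant, effect size is the primary quantity: the two standard
standardized-difference formulas (proportions and means), reported as
integer percents rounded half away from zero, with ≥ 10% as the
conventional flag.

These formulas are validated against a published eight-cluster outcome
table shipped with the package (`referenceOutcomeStats()`): 41 of its 42
ASD cells are reproduced exactly from the published one-decimal group
statistics. The single exception (cluster 4, hospitalized-with-mental-
illness, published 15) computes to 14 from the rounded inputs; 15 is
reachable only from the unrounded underlying rates, so the discrepancy is a
printed-precision artifact, and the test holds that one cell to ±1.

## The synthetic generator

`generateCohort()` emulates the *structure* of an EHR extract: a patients
table (index date, demographics, eligibility fields), a coded event stream
in the 53-week window, and a one-year outcomes table. An archetype plants
a phenotype through: onset week; an intensity profile (`none`, `constant`,
`ramp`, `early_then_fade`); active feature rows with per-week Bernoulli
event probabilities; and outcome parameters. Design choices:

* **Hospitalization counts** are negative binomial — the published
  outcome tables show SD ≫ mean, which a Poisson cannot produce — and
  per-stay length of stay is log-normal (right-skewed), summed over stays.
* **Graded events** carry raw values (labs: 1–3 SD deviations from the
  population mean on either side; vitals: uniform between the upper normal
  edge and the extreme bound), so the encoding path exercises the real
  scoring code.
* **The default suite of eight archetypes** mirrors the qualitative
  taxonomy reported for bipolar prodromes: no prodrome (lowest subsequent
  hospitalization burden), late-onset short, two gradual ramps, three
  early-persistent variants, one early-fading. Archetypes occupy disjoint
  feature rows — the "well-separated" regime — and outcome parameters span
  the published magnitudes (death 0.8–4.6%, hospitalization ~14–50%).
* **Determinism**: one seeded generator, fixed draw order; regeneration is
  bit-identical. Demographics are generated but never used by clustering.

Validation problem sizes, chosen to keep the full suite comfortably
desk-scale: 100 patients per archetype (800 total) for cluster-recovery and
SSE-scan checks, 2000 per archetype (events suppressed) for outcome-rate
calibration, and 3–5 per archetype for pipeline plumbing tests.

What the generator does **not** emulate: realistic code frequency
distributions, free-text notes (symptom events are emitted as structured
records; the keyword matcher is tested on literal fixtures), correlated
comorbidity structure, or visit-driven observation bias. Passing the
recovery tests therefore demonstrates that the pipeline recovers planted
temporal-phenotype structure under its stated assumptions — not that real
bipolar-disorder prodromes form eight clusters.

## Eligibility filters

`eligibilityFilter()` applies the three cohort rules — ≥ 2 disorder
diagnosis codes, ≥ 12 months of system presence before the index and ≥ 12
months after — with per-criterion exclusion counts, attributing each
exclusion to the first failed rule in that order. Thresholds are
parameters.

## Known limitations

* ICD-9 only; the image feature definitions predate ICD-10 and no mapping
  is attempted.
* Keyword symptom matching has no negation handling.
* The default registry's rows 23–60 are a package convention, not a
  reconstruction of any particular deployment's ordering.
* Cluster *memberships* of any real cohort are not reproducible here (real
  data withheld; K-means seeds unreported); the reproducible surface is the
  method's mathematics and the published ASD table.
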