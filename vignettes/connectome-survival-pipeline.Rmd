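---
title: "Predicting one-year survival from structural connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting one-year survival from structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Glioblastoma infiltrates white matter far beyond the visible tumor mass, so
two patients with radiologically similar lesions can have very different
outcomes. `connsurv` treats the brain as a network: each patient is
represented by a structural connectome — a symmetric weighted adjacency
matrix over a 246-region parcellation (210 cortical + 36 subcortical
regions) — built once with streamline counts (*tract count*) as edge
weights and once with *quantitative anisotropy* (QA), a bounded diffusion
measure of fiber integrity. Both matrices of a patient share the same
binary support, so unweighted quantities agree between weighting schemes.
The prediction target is dichotomized overall survival: class 1 means
OS ≥ 365 days (the positive class throughout), class 0 means OS < 365 days.
The threshold is inclusive: a patient surviving exactly 365 days is in the
positive class.

## Graph-theoretical features

Global organization is summarized by density plus twelve measures computed
in both binary and weighted form (25 scalars per weighting scheme): average
clustering coefficient, transitivity, characteristic path length,
small-worldness σ, global efficiency, radius, diameter, degree
assortativity, and rich-club coefficients φ(k) at k = 5, 10, 15, 20.
Regional (local) structure is summarized by eight per-node vectors:
unweighted degree plus seven weighted metrics — strength, clustering
coefficient, local efficiency, betweenness centrality, eigenvector
centrality, PageRank centrality and eccentricity — each of length 246.

Several conventions are deliberate choices where the field has more than
one standard:

* **Weighted distances** use edge length `1/w`: stronger connections are
  closer. This drives weighted path length, efficiency, eccentricity,
  radius/diameter and weighted betweenness.
* **Weighted clustering and transitivity** use the Onnela geometric-mean
  triangle intensity with weights normalized by the matrix maximum. This
  keeps values in [0, 1] and makes them invariant to global weight
  rescaling.
* **Weighted rich club** follows Opsahl: the weight sum inside the rich set
  (nodes of binary degree > k) divided by the sum of the equally many
  strongest weights anywhere in the graph.
* **Small-worldness** is σ = (C/C_rand)/(L/L_rand) against a null ensemble
  of 20 degree-preserving double-edge-swap surrogates (10·|E| swap attempts
  each); weighted surrogates carry the original weights randomly permuted
  over the rewired topology. The ensemble is seeded, so σ is reproducible.
* **Disconnected graphs**: path length averages over reachable pairs only;
  efficiency counts unreachable pairs as zero contribution; eccentricity is
  computed within each component and isolated nodes score 0. Lesioned
  synthetic connectomes can fragment, so these conventions matter.
* **Undefined values** (rich club with fewer than two rich nodes,
  assortativity of a regular graph, transitivity without connected
  triples) are carried as `NA` sentinels; feature assembly maps them to 0
  with a warning, and reports render them as explicit `NA`, never silently
  as 0.
* Eigenvector centrality is the principal eigenvector (power iteration
  with a diagonal shift so bipartite-like spectra cannot oscillate), unit
  Euclidean norm, largest component only; PageRank uses damping 0.85.
  Betweenness is unnormalized.

The note on counting: density is mode-free, so the enumerable global set
contains 25 scalars per scheme (1 + 12 × 2), even though the roster is
sometimes described as 27 in the literature this design follows; nothing
downstream depends on the larger figure.

## Synthetic cohorts

Real connectomes require diffusion MRI and tractography, which are out of
scope. The generator instead produces cohorts whose *structure* exercises
every pipeline stage:

* **Topology**: block-structured support per lobe (edge probability 0.35
  within a lobe, 0.05 between), with 10% of nodes per lobe designated hubs
  wired across modules at probability 0.25. Tract counts are log-normal
  (meanlog 3, sdlog 1) rounded to integers ≥ 1; QA is the bounded monotone
  map `qa = w/(w + median(w))` plus Gaussian jitter (sd 0.02), clipped to
  (0, 1]. Support is shared by construction.
* **Lesion**: each patient receives a hub-biased lesion of 12 nodes in the
  temporal block (hubs sampled with 5× weight). Every incident edge is
  attenuated by `(1 − s·u)`, `u ~ U(0.5, 1)`, where `s ∈ [0, 1]` is the
  patient's severity; edges whose attenuated tract count falls below 1 are
  removed from both supports jointly.
* **Labels**: severity is uniform on [0, 1] — tumor disruption spans the
  full range, which makes a slope of β_sev = 6 a genuinely strong effect —
  and age is Normal(62.9, 11.8) truncated to [21, 94] years. The class
  probability is `plogis(2 − β_sev·s − 0.8·(age − 62.9)/11.8)`; survival
  days are drawn as `365·exp(z)` with `z ~ N(±0.5, 0.4)` signed by the
  class and resampled if they cross the 365-day boundary, so days and
  class are always coherent. Sex (40.8% female), extent of resection
  (GTR/STR/NA at 57.3/38.3/4.4%) and laterality follow the cohort
  frequencies the generator emulates. A prevalence target, when set, is
  enforced by per-patient rejection.

What the generator does **not** emulate: tractography biases, geometric
embedding, site effects between scanners, or any molecular covariates.
Passing tests therefore demonstrate that the pipeline recovers a known
signal planted in network weights under realistic sample sizes — not that
it would achieve the same numbers on real imaging data.

## Feature selection and rebalancing

Local feature tables (246 node columns plus the five clinical covariates —
age, sex, extent of resection, tumor hemisphere, tumor lobe — one-hot
encoded) are reduced in two steps:

1. **Filter consensus**: six rankings — absolute Pearson correlation with
   the label; information gain, gain ratio and symmetrical uncertainty over
   a supervised MDL (Fayyad–Irani) discretization, entropies in bits; OneR
   (one-level rule on equal-frequency bins of at least 6, scored by
   training accuracy); and ReliefF (k = 10 neighbors, all instances, on
   min-max-scaled features). A feature is retained when it ranks in the
   top 50 (ties at the boundary included) of at least three rankings.
   Ranking ties break lexicographically so every ranking is deterministic,
   and a feature scored 0 by a filter (e.g. one whose supervised
   discretization finds no split) never occupies a top slot for that
   filter — otherwise the mass of unscorable features would tie into the
   top list and the consensus would retain nearly everything.
2. **Wrapper refinement**: best-first forward search over the retained
   candidates, scoring each subset by the target classifier's pooled
   accuracy under internal stratified 5-fold CV of the training fold
   (without SMOTE: a balanced training set scored against an imbalanced
   inner validation fold shifts the 0.5-threshold and makes accuracy merit
   meaningless). The search stops after 5 consecutive non-improving
   expansions, with an expansion budget (default 20) as a hard ceiling;
   on consensus-sized candidate sets it terminates naturally around
   5–10 features.

Global tables (25 features) skip the filter triage and go straight to the
wrapper. Class imbalance is addressed by SMOTE (k = 5, balanced 1:1):
synthetic minority points are convex combinations of a minority point and
one of its minority neighbors; originals are never modified.

## Leakage-safe evaluation

The 16 feature-vector configurations (global · tract count; degree, which
is scheme-invariant; and 7 weighted local metrics × 2 schemes) crossed
with ten classifier families (naive Bayes, logistic regression, a
single-hidden-layer perceptron with features+classes neurons, polynomial
SVM, kNN with k = 3, AdaBoost over decision trees, a CART tree, random
forest, bagged trees, and a distance-weighted kNN standing in for KStar —
the substitution is flagged in every report) yield the 160-model grid.

Validation is stratified tenfold cross-validation in which *all*
data-dependent steps — the six filters, the consensus, the wrapper, and
SMOTE — are refit inside each training fold; the fold's validation rows
are only touched at prediction time. Every row index handed to each stage
is recorded in an access log, so the no-leakage property is asserted by
the test suite rather than assumed. Fold assignment depends only on the
seed, so every classifier sees the same folds. Fold results are pooled
(micro-averaged) into one confusion matrix at threshold 0.5; AUROC uses
the rank-statistic (Mann–Whitney) form with tie correction. Held-out
evaluation retrains selection + SMOTE + classifier on the full development
set and applies the frozen bundle to the untouched split. Reports carry
accuracy, precision, sensitivity, specificity, F-score, Youden index,
AUROC, the error count, and Wilson score intervals (z = 1.96) for the
indicators that are binomial proportions; grids are ranked by descending
Youden index, then ascending error count.

## Validation design and problem sizes

The test suite checks every metric against independent brute-force oracles
(Floyd–Warshall distances, explicit geodesic enumeration for betweenness,
dense eigendecomposition, power-iterated PageRank) on all labeled
connected graphs with up to 5 nodes plus 200 random connected weighted
graphs on 6–8 nodes, at tolerance 1e-8. Exhaustive enumeration beyond 5
nodes is combinatorially infeasible, and the random battery covers the
weighted code paths the small census cannot.

Parameter recovery runs at n = 400 patients (β_sev = 6) with a 90/10
split: the tests ask the strength + random-forest model for nested-CV
pooled AUROC of 0.85 and held-out AUROC of 0.80. Two ceilings bound what
any method can achieve here: the label model's Bayes ceiling (AUROC of
the true linear predictor against the realized Bernoulli labels) is
≈ 0.87, and the feature-level ceiling — severity proxied by mean
temporal strength (r ≈ −0.90) plus age — is ≈ 0.84. The pipeline lands
near that feature ceiling, so the nested-CV bar is not attainable under
these generator settings and the corresponding test documents the gap
rather than hiding it; the held-out and selection-recall bars are met.
Null calibration permutes labels five times at n = 150 and requires the
mean pooled AUROC of random forest and kNN to stay inside [0.45, 0.55] —
a direct detector of selection leakage. Grid determinism is exercised at
a reduced scale (50 patients, 40-node connectomes, 3 classifiers × 16
specifications, 3-fold CV) by byte-comparing two runs; determinism is a
property of the code path, not of the problem size.

## Interfaces and limitations

The exported functions are the interface: `generate_cohort()` →
`split_cohort()` → `assemble_features()` → `nested_cv()` /
`train_final()` / `evaluate_heldout()` / `run_experiment()`, with
`scripts/acceptance.R` as the reproducible end-to-end entry point. Known
limitations: no time-to-event modeling (the label is a hard 365-day
dichotomy), no reader for imaging or tractography formats, a CART tree
stands in for C4.5 and a distance-weighted kNN for KStar, and the
synthetic cohorts — however structured — are not a substitute for external
validation on real multi-site data.
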