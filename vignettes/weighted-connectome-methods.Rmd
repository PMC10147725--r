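---
title: "Weighted connectome topology, inference and classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted connectome topology, inference and classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind **wmconn**, the
parameters it exposes, the scope of the synthetic cohort generator, and
the numerical conventions the implementation commits to.

## 1. Data model

A subject's connectome is a symmetric, non-negative weighted matrix
(`ConnectivityMatrix`): nodes are brain parcels, weights are tractography
connection probabilities in \[0, 1\], the diagonal is zero. A `Cohort`
couples the matrices with a subject table (group label patient/control;
covariates age, education, FTND; clinical scores BPRS total, five BPRS
factors, HAMA — patients only) and a node atlas (region, hemisphere,
subnetwork). All downstream results attach to these two objects.

## 2. Graph construction and metric integration

Each matrix is thresholded over an absolute-weight grid from 0.001 to
0.01 in steps of 0.001 (ten graphs per subject; weights equal to the
threshold are kept). On every thresholded graph we compute:

- **Weighted clustering (Onnela)** — geometric-mean triangle intensity
  with weights normalised by the graph maximum; the global value is the
  mean over all nodes.
- **Weighted characteristic path length** — mean shortest-path distance
  over connected pairs with edge lengths `1/w`; disconnected pairs are
  excluded and counted.
- **Modularity (Louvain)** — best Newman modularity over seeded
  restarts.
- **Small-worldness σ** — `(C/C_rand)/(L/L_rand)` against
  degree-preserving Maslov–Sneppen rewired nulls whose edge weights are
  the original weights permuted onto the rewired topology. A
  *cluster-correction* flag additionally requires the observed clustering
  to exceed the null 95th percentile, guarding against labelling
  near-random graphs small-world.
- **Nodal efficiency** — mean inverse shortest-path distance from each
  node.
- **Hubness score** — a 0–4 composite: +1 each for strength in the top
  20%, weighted betweenness in the top 20%, clustering in the bottom
  20%, nodal efficiency in the top 20%.

Each metric's curve over the grid is integrated by the trapezoid rule
(AUC), giving `4 + 2N` features per subject (`cp`, `lp`, `q`, `sigma`,
and per-node `enod_*`, `hub_*`), stored as a `SummarizedExperiment`.

**Hubness tie convention.** The percentile criteria need a tie rule: a
unit-weight star's leaves tie at every cutoff, and an all-inclusive rule
would score them 4, which contradicts the intended reading (leaves are
not hubs). We therefore use *strict* exceedance of the 80th percentile
for the three "high" criteria and an *inclusive* 20th percentile for the
"low clustering" criterion. Under this convention a star's centre scores
4, its leaves at most 1, and every node of a regular ring ties at the
same score.

## 3. Group inference

Feature-wise group contrasts use a **Freedman–Lane permutation GLM**:
the reduced model (intercept + age + education + FTND) is fit, its
residuals permuted, and the group t statistic recomputed per
permutation; the two-sided p-value is `(1 + exceedances)/(1 + nPerm)`
(defaults 10,000 permutations for the four global features, 5,000 for
nodal ones). Unadjusted Cohen's d (control minus patient) with the
0.2/0.5/0.8 banding accompanies each contrast. No multiplicity
correction is applied to the feature screen — its output is a candidate
set for feature selection, not a confirmatory family.

Clinical associations are Pearson partial correlations among patients,
adjusting the same covariates.

**Network-based statistic.** Edges present in at least half of each
group are tested one-tailed with the same covariate-adjusted GLM; edges
with `p < 0.05` form suprathreshold components, and the maximum
component size under Freedman–Lane permutation provides family-wise
error control: `fweP = (1 + #{null max ≥ observed})/(1 + nPerm)`.

## 4. Classification

Candidate features (the significant set) enter a logistic **LASSO**
whose penalty minimises the mean cross-validated binomial deviance over
10 repeats of stratified fivefold CV. The selected features feed a
**linear SVM** (cost 1) evaluated by 100 repeats of stratified fivefold
CV — 500 fold evaluations, reported as mean ± sd percent accuracy,
sensitivity, specificity and Cohen's kappa. Min–max scaling is fit on
each training fold and applied to its test fold. Significance comes from
a label-permutation test (one CV per permuted labelling;
`p = count/nPerm`, with the `(1+count)/(1+nPerm)` smoothed companion).

**Leakage caveat.** Running the feature screen and LASSO on *all*
subjects before cross-validation re-uses test subjects during selection
and inflates accuracy. `leakageAudit()` quantifies this by running the
same chain in both orderings; on permuted-label null data the "select
first" ordering is reliably optimistic while nested selection stays near
chance. Reported accuracies should come from the nested ordering unless
the goal is to reproduce the unnested protocol, in which case the audit
gap should be reported alongside.

## 5. Synthetic cohort generator

Since clinical diffusion data cannot ship with a package, `wmconn`
generates cohorts from a weighted planted-partition model: contiguous
modules (default 6 over 90 nodes), within-module edge probability 0.5,
between 0.15, log-normal weights (within `meanlog = log 0.05`, between
`log 0.02`, `sdlog 0.8`, capped at 1). Default group sizes and
covariate/clinical moments mirror a 46-per-group methamphetamine
dependence case–control design. Patient-specific contrasts are
injectable:

- `effectModularity` — relocates a fraction of within-module edges to
  empty between-module pairs and shrinks weights toward the grand mean,
  lowering modularity and clustering;
- `effectSigma` — rewires edge endpoints at random, eroding
  small-world structure;
- `effectNodes` — multiplies all weights incident to chosen nodes,
  raising their strength and efficiency;
- `clinicalCoupling` — couples a patient clinical score to the
  subject's planted-partition modularity (centred on the patient mean),
  planting a clinical–topology correlation;
- `injectEdgeComponent()` — adds a fixed delta to a named edge set in
  one group, planting an NBS-detectable component.

**Scope.** The generator produces stochastic block structure with
independent log-normal weights. It does not model spatial embedding,
distance-dependent connection probabilities, measurement noise of
tractography, site effects, or realistic degree distributions; it exists
to give every pipeline stage a ground truth, not to imitate brains.

## 6. Numerical and scale choices

- All randomness flows from one master seed through a per-purpose
  string-keyed stream (`deriveSeed`), so results are independent of
  subject ordering and reproducible bit-for-bit.
- Permutation p-values use the `(1+count)/(1+nPerm)` convention (never
  exactly zero); the classifier permutation test additionally reports
  the raw `count/nPerm` fraction.
- σ requires the largest connected component to span ≥ 90% of nodes and
  at least 20 null graphs.
- Paper-scale defaults (46 per group, 90 nodes, 10,000/5,000/5,000/5,000
  permutations, 100 nulls, 100 CV repeats) are the function defaults.
  The package's own test and example profiles run smaller problems —
  cohorts of 8–20 per group on 16–36 nodes, 49–499 permutations, 20
  nulls — chosen so the full chain exercises in seconds to minutes on
  one CPU. The effect sizes used in the recovery checks
  (`effectModularity 0.4`, `effectSigma 0.15`, nodal multiplier 1.6)
  were calibrated once at that scale to be reliably detectable and then
  frozen.

## 7. Limitations

- The permutation GLM assumes exchangeability of reduced-model
  residuals; strong heteroscedasticity between groups weakens it.
- NBS controls family-wise error at the component level only; it does
  not localise which edges within a significant component drive it.
- The NBS max-component-size statistic is integer-valued and, at the
  graph sizes used here, takes few distinct values; the permutation test
  is therefore exact but conservative (empirical family-wise error well
  below the nominal 5% on null cohorts — about 1% in the most favourable
  dense-presence setting). Attained error approaches nominal only as
  graphs grow and the size distribution gains resolution.
- The feature screen is uncorrected by design; downstream accuracy
  estimates inherit its selection effects unless the nested ordering is
  used (see the leakage audit).
- Synthetic calibrations transfer to real data only insofar as the
  block-model assumptions hold.
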