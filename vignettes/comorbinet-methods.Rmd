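---
title: "Methods: disease comorbidity networks from diagnosis trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease comorbidity networks from diagnosis trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Comorbidity — two diseases affecting the same patients more often than
chance — carries information about shared etiology, disease progression and
clinical management. Given inpatient records of the form
(patient, encounter index, ICD-10 code), `comorbinet` builds a Disease
Comorbidity Network (DCN), characterises its topology and community
structure, validates comorbidity strength against shared disease genes and
pathways, and predicts disease occurrence from a patient's earlier visits.
Because real hospital discharge datasets of this kind are not publicly
available, the package ships a synthetic cohort generator with *planted*,
recoverable structure, and the test suite validates the whole pipeline
against that known ground truth.

## Pair statistics and network construction

For diseases $i, j$ with patient-level counts $C_{ij}$ (patients carrying
both), prevalences $P_i, P_j$ (patient counts), and cohort size $N$:

$$RR_{ij} = \frac{C_{ij} N}{P_i P_j}, \qquad
\phi_{ij} = \frac{C_{ij} N - P_i P_j}
{\sqrt{P_i P_j (N - P_i)(N - P_j)}}.$$

$\phi_{ij}$ is exactly the Pearson correlation of the two binary
patient-indicator vectors; the suite verifies this equivalence to 1e-12
against explicitly expanded indicator vectors. A variant of the $\phi$
formula with numerator $C_{ij} - P_i P_j$ circulates in print; it is
dimensionally inconsistent for count-valued prevalences and breaks the
premise that $RR > 1$ and $\phi > 0$ coincide, so the package uses the
binary-Pearson form by default and keeps the printed variant behind
`printed_formula = TRUE` for comparison only.

Counting is **patient-level**: a patient's disease set is the union over all
visits, and a patient contributes at most once to every count. The
denominator $N$ is the generating configuration's patient count when a
synthetic cohort carries its metadata — patients with no diagnoses leave no
rows, and pretending they do not exist biases RR downward under
independence — and the number of distinct observed patients for real record
files, where diagnosis-free patients are genuinely invisible. The DCN
retains pairs with $C_{ij} > 5$, $RR > 1$ and $\phi > 0$ (strict
inequalities, configurable), with the co-occurrence count as edge weight.
Pairs with zero or full prevalence are skipped, not errors.

## Topology and hierarchical modularity

Node measures are computed on the **unweighted** thresholded graph: degree,
betweenness normalized by $(n-1)(n-2)/2$, local clustering $CC_1$ (0 for
degree < 2), and closeness $CC_2$ computed within each connected component
as $(n_c - 1)/\sum d$ (0 for isolates). Average path length averages over
connected pairs only; these disconnected-graph conventions are documented
because the field's reports are usually silent about them. Weighted
shortest-path variants are intentionally out of scope: the reported
clustering/betweenness conventions in this literature are unweighted, and
weights stay available as edge attributes.

A hierarchical modular network shows *decreasing clustering with increasing
degree*: hubs bridge modules whose internal nodes are densely interlinked.
The package reports Pearson correlations (with t-test p-values) for the six
pairs of measures; on the hierarchical synthetic cohort the suite requires
$PCC(k, CC_1) < 0$ and $PCC(k, CC_2) > 0$, the qualitative signature seen in
real DCNs. The heavy-tail diagnostic for degree/weight distributions is a
least-squares slope on log-binned log-log data — deliberately *not* a formal
power-law fit, since only a qualitative scale-free claim is made.

## Community detection

`louvain()` implements the BGLL two-phase loop directly (local moves
maximizing modularity gain, then aggregation, repeated): the environment's
graph library is used for centralities, but the community optimiser is
authored here so that visit order, tie-breaking (first best move in
increasing community-id order) and seeding are fully specified and
deterministic. Weighted modularity over co-occurrence weights is the
default — the DCN is a weighted network and BGLL is weight-aware; the
original report does not state which was used, so unweighted mode is a flag.
Because the greedy phase can stall in local optima on small dense graphs
(and aggregation locks communities together), the optimiser adds *iterated
refinement* — after each multi-level pass the node-moving phase is re-run
initialized from the final partition, so single-node defections remain
possible, cycling while modularity improves — and keeps the best of five
seeded restarts. The suite checks `louvain` against exhaustive enumeration of all set
partitions on graphs of up to 8 nodes (Bell(8) = 4,140 partitions),
requiring at least 95% of the optimal modularity, and exact clique recovery
on the two-clique toy. Planted-module recovery is scored by the Adjusted
Rand Index with threshold 0.9 under strong planting (boost 8); ARI is used
because the original analysis reports no recovery metric.

## The synthetic cohort: what it emulates, and what it does not

The generator encodes the assumptions the analysis relies on:

* **Modular comorbidity.** Diseases are partitioned into modules. Each
  patient's disease set is drawn by sequential conditional sampling in a
  fresh random disease order: once a patient carries one disease of a
  module, every other disease of that module has its probability multiplied
  by `within_module_boost` (default 8, clamped at 0.99). This is the
  simplest mechanism with tunable pairwise dependence and a well-defined
  joint distribution; boost 1 gives exact independence, which the suite
  uses as a null (mean RR in [0.95, 1.05] at 20,000 patients).
* **Hierarchy and hubs.** `generate_hierarchical_cohort()` nests
  sub-modules (level-$l$ boost $= b^{1/2^{l-1}}$, so finer modules are
  tighter) and promotes ~5% of diseases to hubs with 8x baseline prevalence
  (capped at 0.30) and a cross-module boost of 3. Hubs acquire high degree
  with low clustering; leaves the reverse.
* **Heavy-tailed prevalence.** Optionally log-normal baselines
  (`heavy_tail_sdlog`, median at the configured level, capped at 0.5). The
  source data's prevalence distribution is not described anywhere; the
  log-normal is a modelling convenience, not a claim.
* **Visits.** Each patient has 2–5 visits (inpatients with at least two
  encounters); each disease of the patient's set is scattered over visits
  (each visit included with probability 0.6, at least one forced), so the
  per-patient union equals the sampled set exactly and per-visit
  trajectories remain meaningful.
* **Chapters.** Codes are synthetic 4-character ICD-like strings whose
  leading letter is the top-level module, which makes community-composition
  homogeneity measurable.
* **Molecular coupling.** Each module owns a disjoint 30-gene pool; a
  disease with $k$ genes draws $\mathrm{round}(c \cdot k)$ from its pool.
  Coupling $c = 0$ makes gene sharing independent of comorbidity; $c = 0.8$
  plants the positive comorbidity–gene-sharing correlation whose *sign* the
  validation module must recover. Pathways are uniform random gene sets,
  linked to diseases by a configurable minimum gene overlap (default 1),
  the simplest defensible reading of "linking" two association tables.
* **Temporal risk rule.** The target disease appears at a visit with
  probability 0.8 if any planted risk disease occurred strictly earlier and
  0.05 otherwise. Risk diseases get baseline prevalence 0.30 — the scale of
  a common chronic condition — so that the planted mechanism, not the
  background, dominates target occurrence.

What a green test does **not** establish: realistic ICD-10 semantics,
age/sex structure, hospital effects, coding noise, or the actual effect
sizes of any real population. The generator's planted effects are strong by
design; passing recovery tests demonstrates the machinery is correct, not
that weak real-world signals would be detected.

## Trajectory prediction

For a target disease (or a code *set*, e.g. a composite "psychiatric
diseases" target — label 1 if any member occurs), each patient with at
least two visits yields instances at index visits $v \ge 2$: features are
the diseases of visits $< v$ (binary presence, the target always excluded),
the label marks the target at visit $v$. Positives are capped at one per
patient (first occurrence) and instances stop at onset, so eventual cases
contribute only pre-onset negatives.

**Negative sampling.** By default the benchmark's negatives are drawn from
*target-free patients* (incident case-control). The alternative — pooling
pre-onset visits of eventual cases as negatives — caps attainable precision
when the planted trigger is 0.8: a feature-identical instance is negative
whenever the 20% miss occurs, which bounds the Bayes F1 near 0.90 and makes
the 0.9 recovery threshold unreachable in principle. This was derived from
the generative model before measuring; the literal pooled policy remains
available via `exclude_case_patients = FALSE`.

Cross-validation is 10-fold, stratified, and **grouped by patient**, which
prevents leakage of a patient's instances across folds at the cost of
slightly conservative metrics. The four classifier families mirror the
standard settings: L2 logistic regression at regularization intensity 1
(glmnet ridge, $\lambda = 1/n$), a linear max-margin classifier at penalty
10 (primal squared-hinge, L-BFGS — squared hinge keeps the objective
differentiable), a 180-tree random forest (bootstrap, Gini, per-node
$\mathrm{mtry} = \lfloor\sqrt{p}\rfloor$, OOB score, impurity importances;
implemented in C++ for binary features, where every split is "present vs
absent"), and a two-hidden-layer ReLU network (32/16 units, Adam at 0.001,
mini-batches of min(200, n), at most 200 epochs with 10-epoch patience at
tolerance 1e-4). The forest defaults `min_node = 2`, `max_depth = 30`:
depth matters because noise splits on balanced labels are what give the
permuted-label null its per-instance prediction variability (F1 ≈ 0.5);
pruning them too aggressively collapses the forest to a near-constant
predictor.

Risk-disease rankings come from signed coefficients (linear models) and
impurity importances (forest); the network has no comparable per-feature
score and is skipped.

## Numerical and design choices

* Thresholds are strict (`> 5`, `> 1.0`, `> 0.0`); an inclusive flag
  exists because the original wording is ambiguous.
* Degenerate inputs: zero/full-prevalence pairs are skipped with a count;
  zero-variance correlation inputs return NA with a warning; empty
  networks are valid (with a warning); `k` larger than available returns
  everything with a warning.
* Determinism: every generator and every stochastic algorithm takes one
  integer seed; all randomness flows from R's RNG (the C++ samplers use
  R's `unif_rand`), so identical seed means byte-identical output. The
  pipeline derives per-stage seeds by hashing the global seed with the
  stage name (FNV-1a folded below $2^{31}$), making stages independently
  re-runnable.
* p-values are reported exactly and displayed with the conventional
  "< 2.2e-16" floor.

## Known limitations

* The comorbidity measures are symmetric; temporal directionality of
  comorbidity is out of scope (the trajectory module is the only place
  order matters).
* No multiple-testing correction is applied to pair statistics, matching
  the construction being emulated.
* The exhaustive Louvain oracle is feasible only to 8 nodes; beyond that,
  quality is checked indirectly (planted recovery, Q monotonicity).
* Synthetic benchmark metrics are not comparable to the published F1
  scores, which were computed on a proprietary 8.5M-record population.
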