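# comorbinet

Disease comorbidity network analysis from patient diagnosis trajectories.

`comorbinet` is for epidemiologists and systems-biology researchers who have
(or simulate) inpatient diagnosis records — one row per
(patient, encounter, ICD-10 code) — and want to ask: *which diseases
co-occur beyond chance, how is that co-occurrence organised, does it track
shared molecular mechanisms, and can a patient's diagnosis history predict a
future diagnosis?*

## What it computes

For every disease pair with patient-level co-occurrence count $C_{ij}$,
prevalence counts $P_i, P_j$, and cohort size $N$:

$$RR_{ij} = \frac{C_{ij}\,N}{P_i P_j}, \qquad
\phi_{ij} = \frac{C_{ij}\,N - P_i P_j}{\sqrt{P_i P_j (N-P_i)(N-P_j)}}$$

$\phi$ is exactly the Pearson correlation of the two binary
patient-indicator vectors (tested against expanded indicators to 1e-12).
The **Disease Comorbidity Network (DCN)** keeps pairs with co-occurrence
> 5, RR > 1 and $\phi$ > 0, weighted by co-occurrence. On top of that:

* **Topology** — degree, betweenness, clustering (CC1), closeness (CC2),
  degree/weight distributions with a heavy-tail slope diagnostic, and the
  six measure–measure Pearson correlations used to diagnose *hierarchical
  modularity* (negative degree–CC1 correlation).
* **Communities** — an in-package Louvain/BGLL multi-level modularity
  optimiser (weighted by default, seeded, deterministic, with iterated
  refinement), plus community composition against ICD chapters and the
  Adjusted Rand Index for planted-structure recovery.
* **Molecular validation** — shared gene/pathway counts, Jaccard/cosine
  similarities, correlations between comorbidity strength and molecular
  overlap, and binned strength curves.
* **Trajectory prediction** — turn visit sequences into a supervised
  dataset (features = diseases strictly before the index visit, target
  excluded), balanced case-control benchmarks, 10-fold patient-grouped
  cross-validation of four classifiers (L2 logistic regression, linear
  SVM, 180-tree random forest, two-hidden-layer neural network), and
  ranked risk-disease extraction.
* **Synthetic cohorts** — generators with planted modular comorbidity,
  nested hierarchy with hubs, heavy-tailed prevalence, tunable
  gene-sharing/comorbidity coupling, and temporal risk rules; every claim
  in the test suite is validated against this known ground truth.

## Worked example

```r
library(comorbinet)

cc <- cohort_config(n_patients = 20000, n_diseases = 40, n_modules = 4,
                    baseline_prevalence = 0.02, within_module_boost = 8,
                    seed = 1)
records <- generate_cohort(cc)      # 55,413 diagnosis rows
pairs   <- count_contingency(records)
pairs[1:3]
#>    disease_i disease_j  c_ij   p_i   p_j     n       rr       phi
#> 1:      A001      A002    73   641   649 20000 3.509539 0.0836281
#> 2:      A001      A003   101   641   659 20000 4.781982 0.1270312
#> 3:      A001      A004    86   641   629 20000 4.265989 0.1070907

net <- build_network(pairs)         # co-occurrence > 5, RR > 1, phi > 0
net
#> <comorbidity_network> 40 nodes, 426 edges

compute_topology(net)
#> <topology_profile> 40 nodes, 426 edges, <k> = 21.300, <CC1> = 0.599, <path> = 1.454

measure_correlations(compute_topology(net))[1:2]
#>    measure_x  measure_y        pcc      p_value
#> 1:    degree clustering -0.5714287 1.175212e-04
#> 2: closeness clustering -0.5618383 1.616730e-04

part <- louvain(net, seed = 17)
part
#> <community_partition> 4 communities, Q = 0.4753
planted <- attr(records, "cohort_meta")$module_assignment[net$nodes]
adjusted_rand_index(part$assignment, planted)
#> [1] 1
```

Reading: within-module disease pairs show RR ≈ 3.5–4.8 and positive φ (the
planted boost), the network's degree–clustering correlation is negative
(−0.571, the hierarchical-modularity signature), and Louvain recovers the
four planted modules exactly (ARI = 1), each community being 100% one ICD
chapter.

Real data enter through `read_records("records.csv")` (columns
`patient_id,visit_index,icd10_code`; codes are normalized to 4 characters,
rows with missing codes dropped and counted) and
`read_molecular_tables("disease_gene.csv", "pathway_gene.csv")`.

## Pipeline and CLI

A full run from one config file (see `inst/extdata/demo-config.yaml`):

```r
run_pipeline(system.file("extdata", "demo-config.yaml", package = "comorbinet"),
             out_dir = "demo_out")
```

writes `records.csv`, `pairs.tsv`, `edges.tsv`, `topology.tsv`,
`correlations.tsv`, `partition.tsv`, `composition.tsv`, `validation.tsv`,
`prediction_metrics.tsv`, `risk_features.tsv` and a `manifest.json` with
MD5 checksums; identical configs reproduce identical checksums. The same
stages are scriptable via the installed `exec/comorbinet` CLI
(`comorbinet network|topology|communities|validate|predict|run ...`).

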