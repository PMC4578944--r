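# coreGRN

Core-regulator discovery and K-core hierarchy analysis for gene
regulatory networks (GRNs).

## The problem

A condition-specific human GRN — say, the genes differentially
expressed when a hormone-responsive cell line is stimulated — is a
directed graph with thousands of genes, in which every transcription
factor (TF) or microRNA (miRNA) has many targets and every gene many
regulators.  Which of the regulators are *core*, i.e. actually drive
the response?  `coreGRN` is for computational biologists who want to
benchmark answers to that question quantitatively rather than by
inspection.

The package implements an end-to-end pipeline:

* **Network construction** from interaction evidence: ChIP peaks are
  assigned to targets whose TSS falls within ±1 kb of the peak
  interval (window configurable, inclusive at the boundary); miRNA
  targets require consensus of at least 2 of the prediction databases
  supplied; condition-specific networks are induced subnetworks on
  FDR-thresholded differentially expressed genes.
* **Eight regulator-ranking strategies**: |log2 fold change|,
  out-degree, in-degree, target fold enrichment
  `((#DE targets)/(#DE)) / ((#targets)/(#genes))`, closeness,
  betweenness, pagerank (damping 0.85), and K-core depth, all with one
  deterministic tie rule.
* **K-core layered hierarchy**: iterative shell peeling on total
  degree assigns each node a core number; ranking regulators in the
  opposite order of removal puts the most densely interconnected ones
  innermost, and classification sweeps over depth bands (`K<=2`,
  `K==3`, ...) test whether inner layers explain expression better.
* **Expression classification**: with m candidate regulators and n
  labelled targets, `x_ij = 1` iff regulator j directly targets gene
  i and `y_i = ±1` is the expression direction; models are closed-form
  linear regression, the first principal component of the uncentered
  `X Xᵀ` as an unsupervised score, and RBF support vector
  regression/classification with a nested 80/20 grid-search protocol —
  scored by trapezoidal AUROC (equal to the tie-corrected Mann–Whitney
  statistic) and the Matthews correlation coefficient, in seeded
  k-fold cross-validation.
* **Two randomization nulls**: typed node-sampling (is a ranking
  specific to the condition network or inherited from the general
  network?) and degree-preserving edge randomization via the directed
  configuration model (does classification collapse to chance when the
  wiring is destroyed?).
* **A synthetic benchmark generator** with exponential in-degrees,
  heavy-tailed TF out-degrees, and a planted, densely interconnected
  core whose signed weights generate the labels — the ground truth the
  recovery tests measure against.

## Worked example

Generate a benchmark network with 8 planted core regulators, rank
regulators, and test how well the planted core explains expression:

```r
library(coreGRN)

cfg <- synthetic_config(seed = 42)        # 50 TFs, 10 miRNAs, 500 mRNAs
gen <- generate_network(cfg)
gen$network
#> Regulatory network: 560 nodes, 1737 edges
#>   nodes: TF=50, miRNA=10, mRNA=500
#>   edges: TF->TF=80, TF->mRNA=1545, TF->miRNA=6, miRNA->TF=19, miRNA->mRNA=87

deg <- generate_labels(gen$network, gen$truth, seed = 43)
res <- run_all_strategies(gen$network, deg, top_k = 5)
head(subset(res$top_table, strategy == "kcore"), 5)
#>    strategy rank regulator score
#> 36    kcore    1     TF005    10
#> 37    kcore    2     TF006    10
#> 38    kcore    3     TF001    10
#> 39    kcore    4     TF002    10
#> 40    kcore    5     TF007    10
gen$truth$core_ids
#> [1] "TF001" "TF002" "TF003" "TF004" "TF005" "TF006" "TF007" "TF008"
```

The K-core ranking's top entries are planted core regulators (score =
core number; all eight share the deepest shell).  Their edges explain
most of the expression labels, and the inner K-core band beats the
outer band by a wide margin:

```r
labels <- setNames(deg$direction, deg$gene_id)
fm <- build_feature_matrix(gen$network, gen$truth$core_ids, labels)
cross_validate(fm, "LR", k = 5, rng_seed = 1)
#> LR: mean auroc = 0.8762 over 5 folds

core_cutoff_sweep(gen$network, labels, c("K<=2", "K>=3"),
                  models = "LR", k_folds = 5, rng_seed = 1)
#>   selection n_regulators n_targets empty        LR
#> 1      K<=2            8       522 FALSE 0.8790878
#> 2      K>=3           22       508 FALSE 0.5146423
```

An AUROC of 0.88 means the 8 inner-core regulators rank up-regulated
genes above down-regulated ones correctly for 88% of gene pairs; the
22 outer regulators carry almost no signal (0.51 ≈ chance).

`run_pipeline(run_config(output_dir = "out", seed = 1))` runs all
stages (simulate → validate → build → subnetwork → rank → classify →
hierarchy) and writes TSV/JSON outputs plus an md5-stamped manifest;
`inst/cli/corereg.R` wraps this for shell use.

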