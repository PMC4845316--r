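# miconet

Co-occurrence communities of the infant gut microbiome and their
dietary and autoimmune associations.

## What it does, and for whom

For microbiome researchers studying early-life gut ecology, `miconet`
implements an analysis chain that moves between the single bacterium
and the whole community: it identifies *groups* of co-occurring
bacterial genera, then asks whether those groups track infant diet and
the development of persistent islet autoantibodies (seroconversion,
the precursor of type 1 diabetes).

The chain:

1. **Preprocess** 16S-derived OTU counts: keep OTUs with ≥ 50 reads in
   ≥ 10 samples, aggregate classified OTUs to genus, drop genera below
   0.01 % of total reads, and pick per child the stool sample closest
   to age 6 months (within 3–9 months).
2. **Network**: all-pairs Spearman ρ with compositionality-corrected
   p-values (ReBoot permutation/renormalization null vs bootstrap,
   implemented in C++); edge iff ρ > 0.4 and p < 0.05; keep the
   largest connected component.
3. **Communities** by Markov stability,
   `R(t,P) = Σ_blocks Σ_{i,j∈block} [(Π e^{−tL})_ij − π_i π_j]`,
   optimized per Markov time t by a seeded Louvain-style optimizer;
   the community number (> 2) with the longest plateau across log t is
   selected. Genera with ≤ 1 connection stay unassigned.
4. **Stratify** subjects per community: weighted-normalized UniFrac on
   the community-restricted genus abundances, PAM (k-medoids)
   clustering, Calinski–Harabasz choice of k ∈ 2..6, PCoA coordinates
   for plotting.
5. **Associate**: Fisher exact tests (breast-feeding, >3 vs ≤3
   introduced food ingredients, autoantibody composition),
   Kaplan–Meier + proportional-hazards HR for time to seroconversion,
   rank-sum abundance comparisons.
6. **Butyrate**: per-sample ratio of *but* genes (K01034 + K01035,
   butyryl-CoA:acetate CoA-transferase) to *buk* genes (K00634 +
   K00929, phosphotransbutyrylase + butyrate kinase) from a
   PICRUSt-style KO table, compared between subject groups.

A seeded synthetic-cohort generator (`simulate_counts()`,
`simulate_metadata()`, `simulate_ko()`, `simulate_tree()`,
`simulate_bundle()`) produces all inputs with ground-truth labels for
recovery testing. See `vignettes/methods.Rmd` for the models,
assumptions, and every calibration decision.

## Worked example

```r
library(miconet)

sim  <- simulate_counts(seed = 1)                  # 40 children, 60 genera
md   <- simulate_metadata(sim$truth, seed = 1)     # diet + outcomes
ko   <- simulate_ko(sim$truth, seed = 1)           # KO table, but/buk shift
tree <- simulate_tree(sim$table$feature_ids, seed = 1)

report <- run_pipeline(sim$table, md, tree = tree, ko = ko,
                       config = pipeline_config(n_perm = 100, n_boot = 100,
                                                n_points = 24, n_restarts = 6,
                                                seed = 1))
print(report)
```

Output actually printed by that run:

```
miconet pipeline report
  input level: genus (60 -> 60 features, 60 genera)
  window samples: 40 children
  network: 60 nodes, 239 edges (largest component 40)
  communities: k = 3 (plateau span 1.39 log10 t)
  C1: 4 clusters
  C2: 5 clusters
  C3: 5 clusters
  C1 risk cluster HR = 1.32 (log-rank p = 0.622)
  C2 risk cluster HR = 3.39 (log-rank p = 0.0227)
  C3 risk cluster HR = 3.88 (log-rank p = 0.00242)
  but/buk in C3: p = 0.000109 (lower in 'risk')
```

Reading it: the three planted genus communities were recovered
(k = 3, the longest Markov-time plateau spans 1.39 decades). Subjects
were stratified within each community; the community carrying the
planted risk subgroup (labelled C3 here) shows an elevated hazard of
seroconversion in its risk cluster (HR 3.88 against a simulated truth
of 2.8, log-rank p = 0.002) and a significantly lower but/buk
butyrate-gene ratio in that cluster (rank-sum p ≈ 1e-4, planted shift
0.5). `write_report(report, "report.json")` serializes everything;
`inst/cli/miconet.R` exposes `simulate` and `pipeline` subcommands.

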