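# wtnet

Comparing the gut microbiota of two host genotypes from 16S rRNA OTU count
tables. The package is aimed at microbiome analysts who have a
samples-by-OTUs count matrix and a two-group design (e.g. wild-type vs
point-mutant littermates) and want, beyond standard diversity statistics, a
**per-sample discriminant index** with honest cross-validated performance
and a **compositionally aware co-abundance network comparison**.

## What it computes

**The WT-index.** OTU abundances are Hellinger-transformed,
*A<sub>ij</sub>* = √(*n<sub>ij</sub>* / *N<sub>j</sub>*). A redundancy
analysis constrained on the binary genotype factor yields, per OTU, the
fraction of its variability explained by genotype (the R² of its Hellinger
column on the group indicator). OTUs explaining more than 10% are the *key
OTUs*, split by enrichment direction into a reference-enriched set *N* and
a contrast-enriched set *M*, and each sample *j* is scored

> *I<sub>j</sub>wt* = Σ<sub>i∈N</sub> *A<sub>ij</sub>*,  
> *I<sub>j</sub>ki* = Σ<sub>i∈M</sub> *A<sub>ij</sub>*,  
> *I<sub>j</sub>* = *I<sub>j</sub>wt*/|N| − *I<sub>j</sub>ki*/|M| ∈ [−1, 1].

Classification quality is the midrank Mann–Whitney AUC under leave-one-out
cross-validation (the key-OTU selection is refit in every fold) with a
stratified 1000-replicate percentile-bootstrap 95% CI.

**Co-abundance networks.** Within each group, OTUs present in more than 40%
of samples enter SparCC (log-ratio-variance basis-correlation estimation,
Dirichlet resampling, pair exclusion); edges require permutation *P* < 0.05
and |R| > 0.7. Network topologies — density, characteristic path length,
clustering coefficient, Freeman centralization, isolated nodes, degree and
eigenvector-centrality vectors — are compared between groups with
two-sample Kolmogorov–Smirnov tests.

**Support.** Rarefaction (without replacement, averaged over permutations),
observed OTUs / Shannon (base 2) / Faith's PD, Bray–Curtis + PCoA,
deviation-from-baseline trajectories for longitudinal designs, per-phylum
Mann–Whitney with BH-FDR, MANOVA (Pillai) on leading principal coordinates,
and a fully seeded synthetic OTU-table generator with planted ground truth
that backs the whole test suite.

## Worked example

Generate a study-scale cohort (300 OTUs, 15 mice per genotype, 30 + 20
planted differential OTUs at log2 fold change 2, 9000 reads/sample) and run
the discriminant core:

```r
library(wtnet)

spec <- synth_spec(p_otus = 300, n_per_group = c(15, 15),
                   n_ref_enriched = 30, n_contrast_enriched = 20,
                   log2_fc = 2, seed = 2026)
sim  <- synth_community(spec)

A    <- hellinger(sim$table)
fit  <- rda_two_group(A, sim$metadata, spec$groups)
keys <- select_key_otus(fit, threshold = 0.10)
keys
#> key OTU set: |N| = 54 (reference-enriched), |M| = 31 (contrast-enriched), threshold 0.1

mean(c(sim$truth$N %in% keys$N, sim$truth$M %in% keys$M))  # planted recovery
#> [1] 0.98

roc <- loocv_auc(sim$table, sim$metadata, spec$groups, n_boot = 1000, seed = 13)
roc
#> AUC = 1, 95% CI (1, 1), 1000 bootstrap replicates [cv: loocv]
```

98% of the planted differential OTUs are recovered among the key OTUs, and
the leave-one-out cross-validated WT-index separates the genotypes
perfectly at this effect size (on null data the same pipeline gives AUC ≈
0.5; see the test suite). The network side follows the same pattern:

```r
gt  <- prevalence_filter(sim$table, 0.40)
r   <- sparcc(gt, seed = 17)
pv  <- permutation_pvalues(gt, r, n_perm = 200, seed = 19)
net <- build_network(r, pv, p_max = 0.05, r_min_abs = 0.7)
topology(net)
```

The numbered scripts under `analysis/` run the complete workflow
(simulate → diversity → WT-index → networks → group statistics), writing
tables under `results/`; `run_full()` does the same from a single YAML
configuration and two input files, deterministically (re-running an
identical configuration reproduces every output byte for byte). A small
synthetic demo cohort and configuration ship in `inst/extdata/`.

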