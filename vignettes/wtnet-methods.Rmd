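---
title: "Methods: the WT-index, SparCC networks, and their validation on synthetic communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the WT-index, SparCC networks, and their validation on synthetic communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtnet)
```

`wtnet` implements a complete two-genotype gut-microbiota comparison from an
OTU count table: diversity statistics, a genotype-discriminating per-sample
index built on constrained ordination, compositional co-abundance networks,
and the supporting group tests. This vignette explains each model, the
parameters that matter, and exactly what the synthetic-data validation does
and does not establish.

## The data model

All analyses start from a samples-by-OTUs matrix of non-negative integer
counts (`otu_table()`), sample metadata (group, subject, timepoint, housing),
and optionally a rooted phylogeny and per-OTU taxonomy strings. Two TSV
dialects are read: a plain samples-as-rows table, and the classic
OTUs-as-rows `#OTU ID` dialect with an optional trailing taxonomy column;
both are normalized to the samples-as-rows orientation in memory.

Counts are subsampled **without replacement** to a fixed depth (default
9000 reads, 1000 subsampling permutations) before diversity calculations,
because both the observed-OTU count and, more weakly, Shannon entropy are
functions of sequencing depth. The averaged rarefied table feeds diversity;
the raw counts feed the Hellinger transform, which already removes depth
(each transformed row has unit norm), so rarefaction before ordination and
indexing is available behind a flag but off by default. Permutation *k*
draws under seed `seed + k`, so any single permutation can be regenerated
in isolation.

## Diversity

Alpha diversity offers observed OTUs, Shannon entropy in **log base 2**, and
Faith's phylogenetic diversity with the path to the root included — both
conventions chosen to match the QIIME 1 lineage of this analysis style.
Beta diversity is Bray–Curtis,

$$d(x, y) = 1 - \frac{2\sum_i \min(x_i, y_i)}{\sum_i x_i + \sum_i y_i},$$

computed on per-sample proportions by default (a raw-count mode exists for
already-rarefied tables). Principal coordinates analysis double-centres
$-\tfrac12 D^2$ and eigendecomposes; negative eigenvalues, which arise
because Bray–Curtis is not Euclidean-embeddable, are clamped to zero and
excluded from the variance-explained denominator. No Lingoes/Cailliez
correction is applied — the clamped axes are only used for visualization
and for the MANOVA below, which retains leading axes where clamping is
irrelevant.

Longitudinal cohorts are summarized by `distance_to_baseline()`: each
post-treatment sample's Bray–Curtis distance to the mean proportion vector
of its reference unit's pre-treatment (timepoint < 0) samples. The
reference unit is the sample's group by default; a per-subject mode exists
because the two conventions answer different questions (population drift vs
individual drift), and with cage effects the group centroid is the more
conservative choice.

## The WT-index

The discriminant core operates on the Hellinger-transformed abundances
$A_{ij} = \sqrt{n_{ij}/N_j}$. A redundancy analysis constrained on the
binary genotype factor reduces, for a single binary constraint, to the
direction joining the two group centroids of the column-centred matrix;
the fraction of OTU $i$'s variability explained by genotype is then exactly
the $R^2$ of its Hellinger column regressed on the group indicator. This
per-OTU goodness-of-fit is the quantity thresholded for key-OTU selection:
OTUs with more than 10% of their variability explained are retained and
split by the sign of the Hellinger group-mean difference into a
reference-enriched set $N$ and a contrast-enriched set $M$. The per-sample
index is

$$I_{j\mathrm{wt}} = \sum_{i \in N} A_{ij}, \qquad
  I_{j\mathrm{ki}} = \sum_{i \in M} A_{ij}, \qquad
  I_j = \frac{I_{j\mathrm{wt}}}{|N|} - \frac{I_{j\mathrm{ki}}}{|M|},$$

bounded in $[-1, 1]$ since every $A_{ij} \in [0, 1]$; positive values mean
"more like the reference community". The 10% threshold is a parameter
(`threshold` everywhere it appears) — at the study's scale it selects a few
dozen key OTUs; raising it shrinks the key set toward the strongest
discriminators.

Classification quality is summarized by the midrank (tie-corrected)
Mann–Whitney AUC. Cross-validation is leave-one-out and **refits the whole
selection per fold** — transform, RDA, key-OTU selection — so the held-out
sample never influences the key set (the Hellinger transform is per-sample,
so computing it once leaks nothing). Folds where selection fails (empty $N$
or $M$, the usual case on null data) contribute score 0 and are logged; the
alternative of skipping them would bias null AUCs away from 0.5. A fixed
key set can instead be applied to a new cohort by calling `wt_index()`
directly, matching the use of an index derived on earlier trials to score a
later one. The AUC's 95% confidence interval is a percentile bootstrap with
1000 replicates, stratified by class so no resample loses a group —
percentile rather than DeLong because the procedure being mirrored is an
explicit bootstrap.

## SparCC networks and topology

Correlations between OTUs are estimated with SparCC, which infers basis
(absolute-abundance) correlations from the log-ratio variation matrix
$T_{ij} = \mathrm{var}\,\log(x_i/x_j)$ under the sparsity approximation,
solving the $(p-1)$-scaled linear system for basis variances $\omega_i$ and
converting via
$r_{ij} = (\omega_i + \omega_j - T_{ij}) / (2\sqrt{\omega_i \omega_j})$.
Per estimation iteration the fractions are drawn from a per-sample
Dirichlet posterior (counts + 1); strongly correlated pairs ($|r| > 0.1$)
are excluded from the basis system up to 10 times; the reported matrix is
the element-wise median over 20 iterations. These are the published
algorithm defaults. Negative basis-variance solutions (possible in
degenerate corners of the approximation) are floored at a tiny positive
value rather than propagated as NaN.

Edge significance comes from a permutation test: each permutation
independently shuffles every OTU's counts across samples — destroying
inter-OTU correlation, preserving marginals — and SparCC is recomputed with
a reduced number of estimation iterations (default 5; the median is stable
far below 20 for permuted data). Two-sided p-values use add-one smoothing,
$p = (1 + \#\{|R^{perm}| \ge |R^{obs}|\})/(n_{perm}+1)$, so $p = 0$ cannot
occur and the strict $p < 0.05$ edge rule stays meaningful. An edge joins a
pair when $p < 0.05$ **and** $|R| > 0.7$, both strict; only OTUs present in
strictly more than 40% of the group's samples enter. Isolated nodes remain
in the node set, because "number of isolated OTUs" is itself one of the
compared metrics.

Topology metrics follow the Cytoscape NetworkAnalyzer conventions:
clustering coefficient averaged over *all* nodes with degree-<2 nodes
contributing 0 (an exclude mode is available), characteristic path length
averaged over connected pairs only, Freeman degree centralization
$\sum_i (d_{max} - d_i) / ((n-1)(n-2))$, and eigenvector centrality as the
principal eigenvector of the unweighted adjacency restricted to the largest
connected component, max-normalized, with all other nodes at 0. Networks
are compared by two-sample Kolmogorov–Smirnov tests (asymptotic p; degree
vectors are heavily tied, where the exact small-sample p is undefined
anyway) on the degree and centrality distributions, alongside a
side-by-side scalar table.

## Group statistics

Differential phylum abundance collapses relative abundances by taxonomy
rank, tests each taxon with a two-sided Mann–Whitney and adjusts with
Benjamini–Hochberg. The Mann–Whitney p is exact for combined samples of at
most 12 without ties and a tie-corrected normal approximation otherwise,
without continuity correction so that identical samples give exactly
p = 1. Community-level separation is tested by MANOVA (Pillai's trace by
default, Wilks optional) on the smallest set of leading principal
coordinates reaching 80% cumulative variance; with one retained axis this
reduces to the one-way ANOVA F test, which is also how it is tested. The
axis-count rule is data-determined on purpose: a fixed count would be
arbitrary across cohorts of different effective dimensionality.

## The synthetic generator, and what validation shows

`synth_community()` draws per-sample basis log-abundances from a
multivariate normal (optionally with within-block correlation), adds a
group effect of $f \log 2$ to the planted OTUs' means — reference-enriched
OTUs in reference samples, contrast-enriched in contrast samples — closes
to proportions, and draws multinomial counts at each sample's depth.
Everything is deterministic given the seed.

Defaults mirror the study scale and were fixed once: 300 OTUs, 15 samples
per group, 30 reference-enriched and 20 contrast-enriched OTUs, log2 fold
change 2, fixed depth 9000. Between-OTU log-sd 2.0 gives the steep
rank-abundance profile typical of mouse gut communities; within-group
log-sd 1.0 reflects the substantial mouse-to-mouse variability of inbred
cohorts. Planted differential OTUs are drawn from the upper-median
abundance half of the community, since the differential taxa being
emulated include dominant genera; planting effects on vanishingly rare
OTUs would mostly test the sequencing-noise floor rather than the
selection machinery. `synth_longitudinal()` adds per-subject Gaussian
random walks on the basis logs with a group-specific per-day sd (scaled by
the square root of elapsed days), creating the larger
deviation-from-baseline trajectories in the faster-drifting group.

The generator emulates the *statistical* structure the analyses assume —
compositional closure, multinomial counting noise, log-scale group effects,
block basis correlations, subject-level drift. It does not emulate real
taxonomic structure, phylogenetic signal, zero-inflation beyond what the
multinomial produces, chimeras or sequencing error. Passing the validation
suite therefore shows the estimators recover the truth *under the model's
own assumptions* (and stay calibrated when effects are absent); it cannot
certify performance on real sequencing data.

The validation suite checks, among others: planted key OTUs are recovered
(≥ 80%) and LOOCV AUC reaches 0.95 at study scale in 18 of 20 seeds; under
the null the LOOCV AUC distribution centres in [0.3, 0.7] with AUC > 0.9 in
at most 5% of seeds, and the edge rate of permutation-thresholded networks
stays below 1% of pairs; within-block ρ = 0.9 pairs outrank cross-block
pairs in ≥ 95% of comparisons; and all closed-form graph metrics and oracle
equivalences (regression R², exhaustive-pairwise AUC, power-iteration
centrality, ECDF-scan KS, enumeration Mann–Whitney, PCoA distance
reconstruction) hold at tight numeric tolerances. Test problem sizes —
e.g. 60 permutations per null network at 20 OTUs, 200 permutations for
p-value-uniformity checks — were chosen as the smallest instances at which
the binomial/Monte-Carlo error of the checked quantity is comfortably
inside the asserted band.

## Numerical and degenerate-input choices

* All-zero samples are an error in every transform (the Hellinger and
  proportion maps are undefined); all-zero OTUs are fine everywhere and are
  simply never selected, never prevalent, and contribute nothing.
* Constant Hellinger columns get variance explained 0, not NaN.
* Zero group-mean difference excludes an OTU from both key sets.
* PCoA of identical samples returns all-zero coordinates.
* `bootstrap_auc_ci` intervals are percentile quantiles (type 7); with
  perfectly separated scores every replicate AUC is 1 and the interval
  collapses to (1, 1).
* Tie handling: AUC and Mann–Whitney use midranks throughout.
* Edge p-values are **not** multiplicity-adjusted: the procedure mirrored
  applies a raw P < 0.05 with the |R| > 0.7 magnitude filter carrying most
  of the selectivity; `bh_fdr()` is available if a corrected network is
  wanted.
* Seeds: every stochastic operation takes an explicit integer seed;
  internally derived seeds are simple fixed offsets (`seed + k` per
  permutation, documented per function) so no result depends on global RNG
  state.

## Orchestration

`run_full()` executes the entire pipeline from two input files under a flat
validated configuration (`pipeline_config()` /
`read_pipeline_config()`, a YAML key-value file mirrored by function
arguments) and writes per-stage TSVs plus a machine-readable
`summary.json` and `manifest.json`. Outputs contain no timestamps, so a
rerun with an identical configuration is byte-identical — determinism is a
testable contract, not an aspiration. The numbered scripts under
`analysis/` run the same stages as a narrative workflow on generated
cohorts at the study scale.

## Known limitations

* The RDA is implemented only for the single binary constraint this design
  needs; multi-factor or partial RDA is out of scope.
* SparCC's sparsity approximation biases correlations toward zero for rare
  OTUs, whose log-ratio variances are dominated by counting noise; planted
  correlations on rare taxa are recovered in rank order but attenuated in
  magnitude.
* The permutation scheme for edge p-values (per-OTU shuffles) tests the
  no-inter-OTU-correlation null; it does not preserve subject-level
  repeated-measures structure, so longitudinal networks treat samples as
  exchangeable within group.
* Faith's PD requires the tree to cover all observed OTUs; no grafting or
  pruning-with-warning is attempted — missing tips are an error by design.
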