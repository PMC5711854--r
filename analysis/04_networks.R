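#!/usr/bin/env Rscript
# Network stage: per-genotype co-abundance networks on the longitudinal
# (treatment-period) samples. OTUs present in > 40% of a group's samples
# enter SparCC; edges require permutation P < 0.05 and |R| > 0.7. Topology
# metrics are compared between genotypes with two-sample KS tests.

suppressMessages(library(wtnet))

tab <- read_otu_table("results/data/longitudinal_counts.tsv",
                      dialect = "biom_tsv")
meta <- read_sample_metadata("results/data/longitudinal_metadata.tsv")
groups <- c("+/+", "+/R258W")

tops <- list()
for (g in groups) {
  keep <- meta$sample_id[meta$group == g & meta$timepoint >= 0]
  gt <- prevalence_filter(subset_otu_table(tab, samples = keep), 0.40)
  cat(g, ":", length(gt$otu_ids), "OTUs pass the 40% prevalence filter on",
      length(keep), "samples\n")
  r <- sparcc(gt, n_estimation_iter = 20, seed = 17)
  pv <- permutation_pvalues(gt, r, n_perm = 200, seed = 19,
                            perm_estimation_iter = 5)
  net <- build_network(r, pv, p_max = 0.05, r_min_abs = 0.7)
  slug <- gsub("[^A-Za-z0-9]+", "_", g)
  write_network(net, paste0("results/network_", slug, ".tsv"))
  write_network(net, paste0("results/network_", slug, ".graphml"),
                format = "graphml")
  tops[[g]] <- topology(net)
  print(tops[[g]])
}

cmp <- compare_topologies(tops[[1]], tops[[2]])
write.table(cmp$metrics, "results/topology_compare.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("KS test, degree distributions: D =",
    round(cmp$ks_degree$statistic, 3), ", p =",
    signif(cmp$ks_degree$p_value, 3), "\n")
cat("KS test, eigenvector centrality: D =",
    round(cmp$ks_centrality$statistic, 3), ", p =",
    signif(cmp$ks_centrality$p_value, 3), "\n")
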