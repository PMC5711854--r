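#!/usr/bin/env Rscript
# Diversity stage: rarefy the cohort to 9000 reads (100 permutations here;
# the methods default is 1000), compute per-sample alpha diversity and the
# Bray-Curtis PCoA, and score the longitudinal cohort's deviation from its
# group baseline.

suppressMessages(library(wtnet))
dir.create("results", showWarnings = FALSE)

tab <- read_otu_table("results/data/cohort_counts.tsv", dialect = "biom_tsv")
meta <- read_sample_metadata("results/data/cohort_metadata.tsv")

rar <- rarefy(tab, depth = 9000, n_perm = 100, seed = 11)
alpha <- data.frame(sample_id = rar$sample_ids,
                    group = meta$group[match(rar$sample_ids, meta$sample_id)],
                    observed_otus = alpha_diversity(rar, "observed_otus"),
                    shannon = alpha_diversity(rar, "shannon"))
write.table(alpha, "results/alpha_diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("mean Shannon by group:\n")
print(tapply(alpha$shannon, alpha$group, mean))

dm <- bray_curtis(rar)
write_distance_matrix(dm, "results/bray_curtis.tsv")
ord <- pcoa(dm, n_axes = 4)
cat("PCoA axis 1/2 explain",
    round(100 * ord$proportion_explained[1], 1), "% /",
    round(100 * ord$proportion_explained[2], 1), "% of variation\n")
write.table(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates),
            "results/pcoa.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

ltab <- read_otu_table("results/data/longitudinal_counts.tsv",
                       dialect = "biom_tsv")
lmeta <- read_sample_metadata("results/data/longitudinal_metadata.tsv")
dev <- distance_to_baseline(ltab, lmeta,
                            reference = "group_baseline_centroid")
write.table(dev, "results/distance_to_baseline.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
bygroup <- aggregate(distance ~ group + timepoint, dev, mean)
cat("mean Bray-Curtis deviation from baseline (by group x day):\n")
print(bygroup)
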