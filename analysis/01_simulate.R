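#!/usr/bin/env Rscript
# Generate the synthetic cohorts every later stage consumes:
#  - a cross-sectional two-genotype cohort at the study scale (300 OTUs,
#    15 mice/genotype, 30 reference-enriched + 20 contrast-enriched OTUs at
#    log2 fold change 2, 9000 reads/sample), and
#  - a longitudinal cohort (6 subjects/group, days -20..8) whose second
#    group drifts faster after treatment start.
# Tables are written as TSV under results/data/ together with the planted
# ground truth, so each stage can be re-run and checked in isolation.

suppressMessages(library(wtnet))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 2026

spec <- synth_spec(p_otus = 300, n_per_group = c(15, 15),
                   n_ref_enriched = 30, n_contrast_enriched = 20,
                   log2_fc = 2, depth = list(type = "fixed", mean = 9000),
                   seed = seed)
sim <- synth_community(spec)
write_otu_table(sim$table, "results/data/cohort_counts.tsv",
                dialect = "biom_tsv")
write.table(sim$metadata, "results/data/cohort_metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(sim$truth[c("N", "M")],
                     "results/data/cohort_truth.json")
cat("cohort:", length(sim$table$sample_ids), "samples x",
    length(sim$table$otu_ids), "OTUs;",
    length(sim$truth$N), "reference-enriched and", length(sim$truth$M),
    "contrast-enriched OTUs planted\n")

lspec <- synth_spec(p_otus = 120, n_per_group = c(6, 6),
                    n_ref_enriched = 12, n_contrast_enriched = 8,
                    log2_fc = 1, seed = seed + 1)
lsim <- synth_longitudinal(lspec, drift_sd = c(0.1, 0.35),
                           timepoints = c(-20, -10, -3, 0, 1, 2, 3, 8))
write_otu_table(lsim$table, "results/data/longitudinal_counts.tsv",
                dialect = "biom_tsv")
write.table(lsim$metadata, "results/data/longitudinal_metadata.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("longitudinal:", length(lsim$table$sample_ids), "samples over",
    length(unique(lsim$metadata$timepoint)), "timepoints\n")
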