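#!/usr/bin/env Rscript
# Stage 2: non-redundant gene list and promoter-state classification.
#
# Filters decoy clusters, selects one representative isoform per cluster per
# time point (S5p -> S2p -> canonical -> seeded random cascade), calls each
# promoter positive/negative for H3K27me3, S5p and S7p with the 5% tail-cut
# threshold and exclusion filters, and assigns the eight-state classification.

suppressPackageStartupMessages(library(promoterstates))

dir.create("scratch", showWarnings = FALSE)
cohort <- read_cohort("results/cohort")
iso <- filter_clusters(cohort$annotation$isoforms)
cat("Removed decoy clusters:",
    paste(attr(iso, "removed_clusters")$cluster_id, collapse = ", "), "\n")

annotation <- build_nonredundant(iso, cohort$annotation$s5p_isoform_counts,
                                 seed = 20260924L)
write_tsv_table(annotation, "results/nonredundant_genes.tsv")
cat("Isoform selection steps:\n")
print(table(annotation$selection_step))

cls <- classify_cohort(annotation, cohort$regions, cohort$counts)
write_tsv_table(cls$states, "results/promoter_states.tsv")
write_tsv_table(cls$thresholds, "results/thresholds.tsv")
saveRDS(cls, "scratch/classification.rds")  # scratch cache for later stages

cat("\nAnalysis set:", length(cls$analysis_set), "of",
    nrow(cls$state_matrix), "genes\n")
cat("State counts at ESC and day 30:\n")
print(table(factor(cls$state_matrix[, "ESC"], PROMOTER_STATES)))
print(table(factor(cls$state_matrix[, "day30"], PROMOTER_STATES)))
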