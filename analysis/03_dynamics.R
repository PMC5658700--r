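#!/usr/bin/env Rscript
# Stage 3: Polycomb trajectory groups and poised-promoter fates.
#
# Partitions the analysis set into PRC Maintained / Lost / Acquired, times
# de novo acquisition, follows the fates of promoters poised (PRC/S5p) in
# ESCs, and tabulates the ESC -> day 30 state transition matrix.

suppressPackageStartupMessages(library(promoterstates))

cls <- readRDS("scratch/classification.rds")
sm <- cls$state_matrix[cls$analysis_set, ]
k27 <- matrix(sm %in% c("PRC_S5p", "PRC_Only", "PRC_Active", "PRC_S7p"),
              nrow = nrow(sm), dimnames = dimnames(sm))

groups <- prc_dynamics(k27)
cat("Polycomb dynamics groups:\n")
print(table(groups))
cat("Maintained + Lost =", sum(groups %in% c("Maintained", "Lost")),
    "= ESC H3K27me3+ count =", sum(k27[, 1]), "\n")

acq <- transient_acquisition(k27, groups)
cat("\nAcquisition timing (transient = later lost):\n")
print(table(acq$first_acquired, acq$transient))

fates <- prcs5p_fates(sm)
cat("\nFates of", nrow(fates$fates), "ESC PRC/S5p promoters at day 30:\n")
print(table(fates$fates$fate))
cat("Always PRC/S5p:", length(fates$groups$always_prcs5p), "genes\n")

dyn <- data.frame(gene = rownames(sm), dynamics_group = as.character(groups))
dyn$first_acquired <- acq$first_acquired[match(dyn$gene, acq$gene)]
dyn$transient <- acq$transient[match(dyn$gene, acq$gene)]
dyn$prcs5p_fate <- fates$fates$fate[match(dyn$gene, fates$fates$gene)]
write_tsv_table(dyn, "results/dynamics.tsv")

tm <- transition_matrix(sm[, "ESC"], sm[, "day30"])
write_tsv_table(data.frame(from = rownames(tm), as.data.frame.matrix(tm),
                           check.names = FALSE),
                "results/transitions_ESC_day30.tsv")
cat("\nTransition matrix written; total genes:", sum(tm), "\n")
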