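# promoterstates

Gene promoters can be silenced by Polycomb while still holding a *poised* RNA
polymerase II complex — phosphorylated on CTD Ser5 (S5p) but not Ser7 (S7p).
`promoterstates` is an R package plus analysis workflow for studying how this
poised configuration evolves from embryonic stem cells (ESCs) to post-mitotic
dopaminergic neurons across five time points (ESC, day 1, 3, 16, 30). It is
written for computational epigenomics researchers who have per-time-point
ChIP-seq enriched regions and TSS-window read counts for H3K27me3, RNAPII-S5p
and RNAPII-S7p, matched expression tables, and annotation.

The core statistic is a per-gene, per-time-point promoter state. A gene *g*
is positive for mark *m* at time *t* when its 2-kb TSS window overlaps an
enriched region for *m* and its read count exceeds the 5th percentile of the
counts of all window-overlapping genes (the "5% tail cut"); genes whose
positive windows overlap another gene's by > 200 bp, or whose bodies are
nested in another positive gene, are NA. The triple
(H3K27me3, S5p, S7p) ∈ {+, −}³ then maps to eight states — Active
(−,+,+), Inactive (−,−,−), PRC Only (+,−,−), poised PRC/S5p (+,+,−),
PRC/Active (+,+,+) and the three rarer single-mark states. Trajectories over
the five time points partition genes into PRC **Maintained**, **Lost** and
**Acquired** (with |Maintained| + |Lost| = |ESC H3K27me3⁺| by construction),
and the poised ESC promoters are followed to their day-30 fates. Downstream
modules couple states to expression peaking (z > 1.75 on row-standardized
TPM), Polycomb-knockout derepression (FC > 2, KO > 1 FPKM), CpG-island/GC
features, DNA-methylation-valley calling (proximity-clustered hypomethylated
regions ≥ 5 kb), and transcription-factor influence ranks via hypergeometric
tests and a from-scratch preranked gene-set enrichment statistic with a
gene-label permutation null.

Because the study-scale inputs are sequencing data and external resources, a
first-class synthetic-data module generates a miniature multi-omics cohort
with planted ground truth (trajectory groups, expression peaks, knockout
responders, methylation-valley membership, rank bias), so every stage is
testable offline and every number below is recomputable from a seed.

## Worked example

The `analysis/` directory holds the numbered workflow. Stage 1 writes the
synthetic cohort; stages 2–6 classify and analyze it, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_classify.R
Rscript analysis/03_dynamics.R
# ... through analysis/06_enrichment.R
```

Stage 3 prints, for the default 1,000-gene cohort:

```
Polycomb dynamics groups:
Maintained       Lost   Acquired   NeverPRC
       115        195        140        550
Maintained + Lost = 310 = ESC H3K27me3+ count = 310

Fates of 250 ESC PRC/S5p promoters at day 30:
  Active Inactive PRC_Only  PRC_S5p
      90       45       60       55
Always PRC/S5p: 55 genes
```

310 promoters are Polycomb-marked in ESC (31%), of which 250 (81%) are
co-occupied by S5p — poised. The partition identity Maintained + Lost =
ESC-positive holds exactly, and 55 promoters keep the poised state at every
time point. Stage 4 shows why that state matters functionally:

```
Knockout upregulation by ESC promoter state:
     state   n n_up   fraction
1   Active 340    6 0.01764706
2 Inactive 337    6 0.01780415
3 PRC_Only  57    1 0.01754386
4  PRC_S5p 242   71 0.29338843
```

29% of poised promoters derepress when Polycomb is removed versus ~2% of
every other class — recovering the planted probabilities (0.30 vs 0.05).
Stage 5 ties the always-poised group to DNA methylation valleys (58% DMV
overlap vs 2% for poised promoters that resolve to Inactive, with 3× broader
H3K27me3 domains), and stage 6 finds the poised set concentrated at the
high-influence end of the TF ranking (ES = 0.97, FDR < 25%) while Active and
Inactive TFs sit at the low-influence end.

The same machinery is callable directly:

```r
library(promoterstates)
cohort <- simulate_cohort(sim_config(), seed = 1)
iso <- filter_clusters(cohort$annotation$isoforms)
ann <- build_nonredundant(iso, cohort$annotation$s5p_isoform_counts, seed = 1)
cls <- classify_cohort(ann, cohort$regions, cohort$counts)
table(cls$state_matrix[, "ESC"])
```

`run_pipeline(list(input_dir = ..., out_dir = ...))` wires all stages over a
cohort directory and writes a JSON manifest with per-stage gene counts.

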