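---
title: "Classifying promoter RNAPII/Polycomb states across neuronal differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying promoter RNAPII/Polycomb states across neuronal differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterstates)
```

## The model

During differentiation from embryonic stem cells (ESCs) to post-mitotic
neurons, many developmental genes are silenced by Polycomb repressive
complexes while still carrying an RNA polymerase II complex phosphorylated on
CTD serine 5 (S5p) but not serine 7 (S7p) — the *poised* configuration.
`promoterstates` implements the computational machinery to study this
interplay: it classifies every gene promoter, at each of five time points
(ESC, day 1, 3, 16 and 30 of dopaminergic differentiation), into one of eight
occupancy states from three ChIP-seq marks, and follows the resulting
trajectories.

A promoter is described by a triple of positivity calls for H3K27me3 (the
PRC2 mark), RNAPII-S5p (present at active and poised promoters) and
RNAPII-S7p (productive transcription only). The eight combinations map to:

| H3K27me3 | S5p | S7p | state      |
|----------|-----|-----|------------|
| +        | +   | −   | PRC/S5p (poised) |
| +        | +   | +   | PRC/Active |
| +        | −   | −   | PRC Only   |
| +        | −   | +   | PRC/S7p    |
| −        | +   | +   | Active     |
| −        | −   | −   | Inactive   |
| −        | +   | −   | S5p Only   |
| −        | −   | +   | S7p Only   |

### Positivity calls

A gene is positive for a mark at a time point when (i) the 2-kb window
centered on its TSS overlaps an enriched region for that mark and (ii) its
read count in the window is above a threshold, set per mark and time point as
the 5th percentile (linear-interpolation quantile) of the counts of all
window-overlapping genes — a 5% tail cut that removes genes whose window
touches an enriched region with negligible signal. We read "above" as strict
(`inclusive = FALSE`); the alternative inclusive reading is a single
configurable switch and moves calls only at exact-threshold ties.

Two exclusion filters then guard against double-counted signal. Positive
genes whose TSS windows overlap by more than 200 bp (10% of the window)
cannot be attributed their own signal; both genes of such a pair become NA
(removing only the lower-count gene is available via `remove = "lower"`, but
the symmetric default makes no claim the data cannot support). A positive
gene whose body lies entirely inside another positive gene's body is likewise
set to NA (the internal gene only). Genes NA for any mark at any time point
are excluded from all downstream analyses — NA is sticky by design, because a
gene with one unattributable call cannot contribute a complete trajectory.

### Isoform selection

Gene clusters may contain several isoforms; one representative is chosen per
cluster per time point by a cascade: highest S5p count in the TSS window,
then highest S2p count in a 4-kb TES window among the tied survivors (S2p
data are optional; without them the cascade skips this step), then the unique
canonical isoform among survivors, then a seeded random draw. The random step
sorts survivors lexicographically before drawing so the result is independent
of input order; the per-cluster seed is derived deterministically from the
cluster identifier. Clusters on chrM or `*_random` scaffolds, and clusters
with no RefSeq-linked isoform, are removed first. The TSS of a minus-strand
transcript is its `txEnd`; windows are clamped at chromosome start.

### Trajectories

With the per-time-point states in hand, genes partition by H3K27me3
trajectory into **Maintained** (positive at all five points), **Lost**
(positive in ESC but not at all five) and **Acquired** (negative in ESC,
positive later). A gene that loses the mark mid-course and regains it at day
30 counts as Lost: this is the unique reading under which Maintained + Lost
equals the ESC-positive count and the three groups sum to the
ever-positive count, identities the package asserts on every run. Among
Acquired genes, those negative again after their first acquisition are
flagged *transient*. Promoters poised (PRC/S5p) in ESC are followed to day
30: staying PRC/S5p at every time point ("Always PRC/S5p"), resolving to PRC
Only (losing S5p), resolving to Inactive (losing both marks), or activating.

## Downstream couplings

**Expression.** Gene-level TPM rows are standardized to z-scores using the
sample (n − 1) standard deviation — with five time points the selection cut
of z > 1.75 is close to the maximum attainable value of
(n − 1)/√n ≈ 1.789, so only genes with one sharply elevated time point and
four flat ones qualify; the population-sd variant is available and widens
the range to 2. A peaking gene must additionally exceed 1 TPM somewhere, and
genes above the cut at two or more time points are not single-time-point
peaks (at n = 5 and sample sd this cannot occur, but the rule is enforced
for generality). Log-scale displays add a 10^-4 pseudo-count.

**Knockout derepression.** From wild-type/knockout expression pairs, a gene
is upregulated when KO/WT > 2 and KO > 1 FPKM; the WT denominator is floored
at 10^-6 so silent-WT genes register as derepressed rather than dividing by
zero. Genes in repressed states (PRC/S5p, PRC Only, Inactive) already above
1 FPKM in wild type are unlikely to carry a truly repressed promoter and
leave both numerator and denominator before per-state fractions are taken.

**Methylation and sequence features.** Hypomethylated regions are
proximity-clustered — transitively merged when gaps are at most `max_gap` —
and merged territories of at least 5 kb (inclusive; the boundary is
configurable) are DNA methylation valleys. The clustering distance is not
derivable from the source material; the default of 1,000 bp is exposed as a
parameter, and the DMV set is provably monotone in both knobs, so conclusions
of the "poised promoters sit in valleys" kind are stable against reasonable
choices. A promoter is classed DMV > hypomethylated > methylated by overlap
priority. Polycomb-domain breadth is the length of the longest enriched
region overlapping the TSS window; GC content excludes N bases from the
denominator; CpG islands are merged before coverage fractions; metagene
profiles average coverage in 10-bp bins with minus-strand profiles reversed
and out-of-chromosome bins dropped from the mean rather than zero-filled.

**Enrichment statistics.** Promoter-state enrichment in gene lists uses
one-sided hypergeometric tails in both directions, reported raw (no
multiple-testing correction across states). TF influence ranks (lower = more
influential) are averaged per TF over conversions, then converted to ranking
scores `max_rank − rank + 1` so high influence sits at the top. The preranked
enrichment statistic is the classic weighted running sum: walking the ranked
list, set members add `|score|^p / Σ|score_hits|^p` and non-members subtract
`1/(N − n_set)`; the enrichment score is the signed maximum deviation. The
weight exponent defaults to 1 (0 gives the unweighted Kolmogorov–Smirnov
form) and the null is 1,000 gene-label permutations — the only null
available for preranked input — under a caller-supplied seed. NES divides by
the mean absolute same-sign null score; with several sets, the FDR is the
standard pooled positive/negative procedure. Ties in scores are broken by
stable identifier order.

## The synthetic cohort

Real inputs for this design are sequencing-scale and external; the package
therefore ships a generator whose defaults *are* the study conditions, with
planted truth for every claim the pipeline makes:

* 1,000 gene clusters on two 10-Mb chromosomes (evenly spaced, so no filter
  fires unless companion overlapping/nested genes are requested), plus chrM,
  `*_random` and RefSeq-less decoy clusters, and extra isoforms in a quarter
  of clusters whose S5p counts keep the primary isoform strictly maximal.
* Trajectory archetypes with fixed fractions: ~31% of promoters
  H3K27me3-positive in ESC, ~81% of those S5p co-occupied, poised promoters
  that persist (5.5%), lose S5p (6%), resolve to Inactive (4.5%) or activate
  (9%), and acquisition waves at day 1 (transient), day 16 and day 30.
* TSS-window counts from a negative binomial (mean 150, size 20) at planted
  positives. Planted negatives carry either no enriched region (background
  counts, mean 20) or, with probability 0.2, a region with zero reads. These
  zero-count decoys are what the 5% tail cut is for: they pin each threshold
  at zero, the strict comparison removes exactly them, and planted states are
  recovered at 100% — which is the property the recovery tests assert.
* H3K27me3 regions three times broader (6 kb vs 2 kb) at always-poised genes;
  TPM lognormal and coupled to S7p; expression peaks planted as one ~100-fold
  elevated time point; knockout derepression probabilities 0.30 (PRC/S5p) vs
  0.05 (PRC Only) with 5% of repressed genes planted WT-expressed to
  exercise the exclusion; methylation-valley membership 0.65 / 0.13 / 0.02
  for the three poised fates; and TF ranks biased low for poised TFs
  (latent-score shift 1.5; 0 gives calibrated-null ranks).

Everything is deterministic under a master seed (per-stage derived streams,
all below 2^31), and written files are byte-identical across runs.

What the generator does **not** emulate: read-level noise and mappability,
peak-caller boundary error, correlated replicates, isoform-level expression,
or any relationship between sequence composition and signal — CGI/HMR tracks
are planted by group, not computed from sequence. Passing tests therefore
demonstrate the correctness of the classification and statistics on data
satisfying the model's assumptions, not robustness to artifacts of real
sequencing data.

## Numerical choices and degenerate inputs

* Quantile type 7 (linear interpolation) for the tail cut; a sort-based
  oracle cross-checks it in the tests.
* Strict threshold comparison by default (see above); both choices tested.
* All coordinates 0-based half-open; conversion to the 1-based closed
  convention of `GenomicRanges` happens in one place (`bed_to_gr`).
* Constant expression rows get z = 0 and a degenerate flag, never selected.
* Two genes with identical bodies are each internal to the other and both
  removed by the containment filter.
* An empty overlapping-count vector (a mark with no enriched regions) is an
  error, not a silent zero threshold.
* Running-sum extremes that tie in magnitude at both ends are resolved by
  first occurrence; such exact ties essentially require symmetric toy inputs.

## Problem sizes

The shipped analyses and tests use the 1,000-gene default cohort for
end-to-end recovery, cohorts of 120–800 genes for module-level checks,
exhaustive hypergeometric enumeration to universe size 25, 500 random
interval sets for the merge oracle, and 200 random gene sets at 200
permutations for the null-calibration check — sizes at which the full suite
runs in a few minutes on one core while every statistical check retains
useful power.

## Limitations

The package classifies promoters from *given* enriched regions and counts;
peak calling, read alignment and expression quantification are out of scope.
Thresholds are per mark and time point and assume libraries of comparable
depth (no cross-library normalization is attempted). The GSEA FDR for a
single set reduces to the permutation p-value; pooled FDR needs several
sets. Identifier matching across datasets is exact and case-sensitive, as in
the homolog and knockout joins.
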