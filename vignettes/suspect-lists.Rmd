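---
title: "Building and validating CUT&RUN suspect lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating CUT&RUN suspect lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suspectr)
```

## The model

A CUT&RUN negative control profiles chromatin with a non-targeting
antibody (or no antibody), so its expected signal is the background of
MNase digestion: fragments scattered essentially at random, modulated by
accessibility. Empirically, a set of regions departs from this
expectation reproducibly — high signal blocks that recur across negative
controls from unrelated cell types, protocols and labs. Any peak caller
scoring signal against global background will call them, and they are by
construction false positives. A *suspect list* is the consensus of these
regions across a panel of N controls.

The package treats the problem as consensus interval detection:

* Per-sample evidence is a SEACR-style **signal block**: a maximal run of
  strictly positive fragment coverage, scored by its AUC
  (sum of coverage over its basepairs) and maximum height. Numeric
  thresholding at fraction $t$ retains the top $\lceil tB \rceil$ of $B$
  blocks by AUC, keeping ties with the cutoff; *stringent* mode also
  requires the block's maximum height to reach the same-rank cutoff of
  the height distribution. This captures the stringent/relaxed contrast
  of the original caller without claiming bit-for-bit agreement with its
  internals, which are not specified by its published description.
* Cross-sample evidence is **segment support**: after extending peaks
  symmetrically and merging within samples, the genome is segmented at
  every peak boundary and each segment is labelled with the number of
  distinct samples covering it. Support counting is per-basepair rather
  than per-whole-peak: it is order-independent, testable against a
  brute-force oracle, and robust to peaks that partially overlap.
* The consensus rule keeps segments whose support fraction strictly
  exceeds $r$: $k = \min\{k : k/N > r\}$. With the published conditions
  ($N = 20$, $r = 0.30$) this gives $k = 7$. The strict inequality
  matters: 6/20 is exactly 30% and is excluded.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `threshold` ($t$) | 0.001 | fraction | top share of signal blocks called per sample; 0.001 keeps the highest 0.1% of signals |
| `mode` | stringent | — | AUC rule plus max-height rule (relaxed: AUC only) |
| `extension` ($e$) | 1000 | bp | symmetric peak growth before overlap, absorbing inter-dataset shifts |
| `min_frac` ($r$) | 0.30 | fraction | reproducibility threshold, strict inequality |
| `bin_size` | 10000 | bp | genome-wide summary bins for correlation/PCA/distances |
| `include_chrM` | TRUE | — | append the mitochondrial chromosome as one policy region |

The mitochondrial genome is included wholesale rather than being asked to
pass thresholds: mitochondrial reads are a known contaminant of the
assay, and their inclusion is a deliberate policy, flagged per region as
`chrM_policy` and toggleable. Unplaced or random scaffolds, by contrast,
must pass the support threshold like any other sequence in the layout.

## Coordinate conventions

Every file boundary (chrom.sizes, BED, bedgraph) is 0-based half-open,
and all emitted intervals satisfy $0 \le \mathrm{start} <
\mathrm{end} \le$ chromosome length. Internally intervals live in
`GRanges` (1-based closed), the standard container of the Bioconductor
interval stack; conversion happens exactly once at each boundary. Output
sort order is layout (file) order then start — chromosomes are never
reordered lexicographically. Fragments are extracted from BAM using
properly-paired flags, reading each pair off its leftmost mate (positive
template length) and ignoring secondary/supplementary alignments;
improper pairs are skipped and counted.

## Numerical choices

* **Tie handling in the caller.** The rank cutoff is the value of the
  $\lceil tB \rceil$-th largest AUC; every block tied with it is kept.
  The retained fraction is therefore in $[t,\ t + \mathrm{ties}/B]$,
  which is asserted as a property test.
* **Control-calibrated calling** uses the inverse-ECDF (type-1) quantile
  of the control's (optionally total-signal-rescaled) AUC distribution,
  so a target identical to its control retains exactly a $t$ fraction.
* **The support threshold** computes $k = \lfloor Nr \rfloor + 1$ with
  the product snapped to the nearest integer when within $10^{-9}$,
  because $20 \times 0.30$ is not exactly 6 in binary floating point and
  the strict rule must not flip on representation error.
* **Knee detection** on the reproducibility curve takes the support level
  maximizing perpendicular distance to the chord between $m = 1$ and
  $m = N$; a constant curve has no knee and is reported as 1 with a flag.
* **Merging** unions overlapping *and* touching intervals (gap 0), the
  default of the standard merge tool.
* **Degenerate inputs.** An all-zero track yields no blocks; an empty
  block list is a warning and an empty peak set; a control with no signal
  is an error; FRIP of an empty fragment set is an error rather than 0/0;
  a zero-variance sample's correlations are reported as `NA` and flagged,
  never coerced to 0.

## Filtering and evaluation semantics

Overlap means $\ge 1$ shared basepair everywhere: fragment filtering
(`bedtools intersect -v` semantics), retrospective whole-peak removal (no
trimming), FRIP's numerator, and list-vs-list region sharing. A direct
consequence, asserted as an identity test: FRIP over a list of any
fragment set filtered by that list is exactly 0.

For the before/after comparison, the after side removes list-overlapping
fragments *and* drops list-overlapping bins from the summary matrix,
mirroring the blacklist option of the genome-summary tools used for this
analysis. Keeping the emptied bins would add a block of concordant
all-zero ties to every sample and bias rank correlations upward.

Two open choices were fixed as follows. The distance ratio uses Euclidean
distance between samples on the full binned count matrix; the space in
which the published ratios were computed is not stated, so exact
reproduction of particular ratios is not claimed, and the statistic is
reported prominently enough for users to substitute alternatives. The
low-mappability flag uses the regional mean of a user-supplied
mappability track with a 0.5 cutoff, again because the published
criterion is unstated; both the mean and the flag are stored per region.
Promoter windows for annotation are TSS −1000/+100 bp (strand-aware),
with precedence promoter > exon > intron > intergenic, and the closest
TSS is assigned from the region midpoint with a sign that is negative
upstream of the TSS in gene orientation.

## The synthetic generator

`simulate_negative_panel()` emulates the statistical structure of a
negative-control panel, not its sequence content: uniform background
fragments (Poisson per chromosome at `background_rate` per kb), shared
artifact regions enriched `artifact_fold`-fold in a Bernoulli(prevalence)
subset of samples drawn once and recorded, per-sample private artifacts
(cell-type-like), normal fragment lengths, and PCR duplicates appended at
`duplicate_rate`. All randomness flows from one seed through a documented
sub-seeding rule (stream $i$ for sample $i$), so panels are byte-stable
and adding samples never perturbs existing ones. Ground truth records
*realized* membership, so tests compare against what was actually
planted, not its expectation.

Defaults were chosen once as plausible study conditions at desk scale: a
2 × 10 Mb + 16 kb chrM genome; 20 samples (the published panel size);
background 2 fragments/kb (tens of thousands of fragments per sample, the
order of a downsampled control); 25 artifact regions of mean 3 kb, so that after 1 kb extension and
merging the consensus regions land at the few-kb scale typical of such
lists, placed with ≥ 20 kb separation so that extension never fuses
distinct truth regions;
50× enrichment; prevalence classes {1.0, 0.6, 0.4, 0.2, 0.05} spanning
both sides of the 30% rule; fragment length 150 ± 30 bp; duplicate rate
0.10. `simulate_target_experiment()` adds true binding sites on the same
artifact placement for target-vs-control calling.

What the generator does **not** model: sequence-driven artifact
mechanisms (satellite/simple repeats, mappability), accessibility
gradients, chromosome-scale coverage imbalance, GC bias, and read-level
errors. Passing tests therefore demonstrate that the consensus machinery
recovers planted reproducible enrichment under realistic counting noise —
not that a list built on any 20 real controls is complete or minimal for
a real genome. Scale matters too: the synthetic genome is ~150× smaller
than a mammalian one while artifact regions are nearly full-size, so
genome fractions and FRIP values on synthetic panels are correspondingly
larger than the published dataset-scale values and are not comparable to
them.

## Problem sizes

The test suite and the acceptance script run entirely at desk scale,
chosen so the full suite completes in a few minutes: oracle equivalence
on ≥ 100 randomized instances with chromosomes ≤ 10 kb; parameter
recovery on ten 20-sample panels over the default 2 × 10 Mb + chrM
layout; evaluation statistics at 10 kb bins (~2000 bins × 20 samples);
the distance-ratio experiment on two targets × three replicates.

## Known limitations

* The numeric-threshold caller is a contract-level model of the original
  signal-block caller; exact agreement with its output is not claimed
  (its total-signal curve and normalization internals are not described
  in its published summary).
* Support counting is segment-based; a tool that counts support per
  original peak would give slightly different region boundaries at
  partial overlaps.
* The BAM reader requires coordinate-sorted, properly-paired input and
  deliberately has no CRAM or single-end support.
* Lists built on one assembly are not lifted over to another; build per
  assembly instead.
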