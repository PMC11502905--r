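---
title: "Methods: ligand-receptor cross-talk screening for plate-based scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-receptor cross-talk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrperm)
```

# Overview

`lrperm` implements the bespoke computations of a sorted-plate single-cell
RNA-seq study of cell-cell communication: two FACS-sorted populations
(microglia and neural stem/precursor cells, NSPCs) collected on 384-well
plates across three time points (uninjured, day 1 and day 7 after a
photothrombotic cortical stroke). The package covers cell quality control,
library-size log-normalization, a permutation-based ligand-receptor
interaction screen, Wilcoxon marker detection with signature-overlap
tabulation, and a seeded simulator with planted ground truth. Clustering,
dimensionality reduction, automated annotation, pseudotime and GO
enrichment are deliberately out of scope: cell-type and time-point labels
are *inputs* here.

# Cell quality control

Three rules are applied, in order, each cell attributed to the first rule
that removes it:

1. **Doublet exclusion.** Wells that received two cells carry roughly
   twice a singlet's library. A cell whose total UMI count exceeds
   `median + k * MAD` of the pre-filter library-size distribution is
   discarded (`k = 3`). The rule is one-sided: a low library is a quality
   problem, not evidence of a doublet.
2. **UMI floor.** Cells with fewer than 1000 total UMIs are discarded.
   The floor is inclusive — a cell with exactly 1000 UMIs is retained —
   with an exclusive variant behind `umi_strict`.
3. **Mitochondrial ceiling.** Cells with more than 25% of their library
   on genes whose symbol starts with `mt-` (matched case-insensitively by
   default) are discarded as dying cells.

Two numerical choices deserve a note. The MAD is the *unscaled* median of
absolute deviations from the median; the 1.4826 normal-consistency factor
is available as `mad_constant` but off by default. For an approximately
normal library-size distribution the unscaled rule at `k = 3` sits at
about `median + 2 sigma` and therefore flags roughly the upper 2% of
singlets along with the doublets; with `mad_constant = 1.4826` the
threshold moves to `3 sigma` and the singlet loss drops below 1%. Both
behaviors are exercised by the test suite. When the MAD is zero (heavily
tied libraries) the threshold degenerates to "above the median", which is
documented rather than special-cased.

# Normalization and group means

Counts are normalized with the standard LogNormalize convention:
`value = ln(1 + count / library * scale_factor)` with a scale factor of
10,000. Log base and scale factor are configurable. Two invariants pin the
implementation down: zeros are preserved exactly, and for every cell with
a non-empty library the back-transformed values `exp(value) - 1` sum to
the scale factor (relative error below 1e-8; in practice machine
precision). Cells with empty libraries map to all-zero columns with a
warning — they should not survive QC in the first place.

Group means are arithmetic means of the log-normalized values over *all*
cells carrying a joint (cell type, time point) label, zeros included, not
means over expressing cells only. This is the literal reading of "average
expression by one cell type" and makes the interaction score reproducible
from the exported group-means table alone.

# The ligand-receptor screen

For a pair (L, R), a sender population A, a receiver population B and a
time point t, the interaction score is

    score = ( mean_A,t(L) + mean_B,t(R) ) / 2 ,

the mean of the average log-normalized ligand expression in the sender
and the average log-normalized receptor expression in the receiver.

Significance comes from an empirical permutation null in the style of
CellPhoneDB. The *joint* (cell type, time point) label vector is randomly
permuted across all cells — one shuffle moves both classifications
together, preserving their co-occurrence structure — group means are
recomputed under the shuffled labels, and every pair is re-scored. One
shuffle serves every pair, so `n_perm = 1000` (the default) means 1000
global label permutations. Shuffling the two label columns independently
is available behind `shuffle_mode = "independent"`; we default to the
joint shuffle because it preserves the label multiset exactly, which
guarantees no permuted group is ever empty.

The p-value is the proportion of null scores greater than or equal to the
observed score. Ties count toward the numerator and `p = 0` is attainable;
the optional `(count + 1) / (n_perm + 1)` estimator exists for calibration
studies but is off by default, matching the plain proportion definition.
The tie comparison carries a 1e-9 relative tolerance so that a shuffle
which happens to reconstruct the observed grouping scores as a tie rather
than falling a rounding error short. No multiple-testing correction is
applied to the permutation p-values by default.

Each pair is scored in both directions by default (`direction_mode`),
since either population can play the ligand role; results carry explicit
sender and receiver fields, and `chord_adjacency()` reduces a result table
to the square sender-by-receiver matrix behind a chord diagram.

# Marker detection and signature overlap

Differential expression uses a two-sided Wilcoxon rank-sum test per gene
over the full gene universe, with midranks for ties. The p-value is exact
— every assignment of the combined ranks is enumerated — whenever
`choose(n, m) <= 10000` (covering all samples up to about 7 + 7), and a
normal approximation with tie correction and continuity correction
otherwise. The split is a correctness/tractability trade-off: enumeration
is feasible and exact on small groups, and the approximation error is
below 0.05 already at 8 + 8 observations.

Bonferroni correction multiplies by the number of genes *tested* (the
full universe), not the number retained. A gene is retained as a marker
iff `log2FC >= 0.25` and adjusted `p < 0.001`. The fold change is computed
on back-transformed group means, `log2((expm1(m_in) + eps) /
(expm1(m_out) + eps))` with `eps = 1e-9`, the convention of the
widely-used marker-test implementations; the pseudocount is configurable.

Signature overlaps (shared-versus-unique tabulation of two curated DEG
sets) report exact set sizes plus a one-sided hypergeometric enrichment
p-value — the probability of at least the observed intersection when
drawing `|B|` genes from the universe with `|A|` successes. The choice of
the hypergeometric test is this package's own; the overlap counts
themselves are test-free.

# The synthetic-data generator

`generate_dataset()` stands in for the deposited experimental data and
defines the conditions under which the package validates itself:

* **Design.** Three 384-well plates — 1152 cells before QC — with cells
  assigned to two populations (50/50) and three time points (uniform) by
  multinomial sampling, emulating sorted plates.
* **Counts.** Gene-wise negative binomial, the standard overdispersed
  model for UMI data. Per-gene means are log-normal (`meanlog = log 4`,
  `sdlog = 1`, spanning roughly two orders of magnitude as real UMI data
  do) with a shared dispersion (`size = 2`), giving libraries of ~3000
  UMIs, typical of plate-based protocols.
* **Mitochondrial block.** The 13 protein-coding mouse mitochondrial
  genes (`mt-Nd1` … `mt-Cytb`) are reserved and scaled so a healthy
  cell's expected mito share is 5%.
* **Artifacts.** A configurable fraction of wells (default 3%) receives
  the sum of two independently drawn cells (doublets); a further 5% are
  dying cells whose library is re-allocated so the mito share reaches
  40%, safely above the 25% QC ceiling.
* **Planted truth.** Markers multiply a gene's mean in one cell type by a
  fold; ligand-receptor plants multiply the ligand mean in (sender, t)
  and the receptor mean in (receiver, t). The ground truth is returned
  with the data, so recovery tests are self-contained.

What the generator does *not* emulate: batch effects across plates,
ambient RNA, gene-gene correlation beyond the planted effects, barcode
errors, and empty wells. Passing recovery and calibration tests on this
generator therefore demonstrates the correctness of the computations, not
robustness to every artifact of real plate data.

# Validation studies and problem sizes

The test suite and the acceptance script re-derive the package's claims
at the following scales, chosen to make the studies statistically
informative while remaining quick to re-run:

* *QC oracle*: 200 random matrices up to 30 genes by 50 cells, compared
  against an independently coded brute-force filter.
* *Calibration*: three independent null plates (384 cells, 400 genes),
  125 pairs at 3 time points in 2 directions — 2250 pair-conditions at
  200 shuffles. Under exchangeable labels the expected fraction of
  conditions with `p <= 0.05` is 11/201 ≈ 0.0547 (the observed score is
  one more draw from the null), and the measured fraction falls within
  0.05 ± 0.02.
* *Exhaustive oracle*: 6-cell instances where all 20 distinct label
  assignments are enumerated; sampled p-values at 500 shuffles are
  checked against 99% binomial intervals around the exhaustive value.
* *Recovery*: single plates with one pair planted at 4-fold elevation on
  randomly chosen genes, screened against 40 decoy pairs at 200 shuffles,
  across 20 seeds.

# Known limitations

* A fold-`f` plant multiplies the *count-scale* mean, which raises the
  log-scale group mean by only about `ln f`. At 4-fold elevation the
  planted pair is essentially always significant (`p <= 0.05` in 20/20
  seeds), but when the planted genes happen to sit in the weakly
  expressed tail of the log-normal baseline, the pair's absolute score
  need not reach the top decile of the panel — pairs of two naturally
  high-expression genes can outscore it. Score rank and p-value answer
  different questions, and only the p-value is calibrated against the
  null; rankings by raw score inherit baseline expression differences.
* Empirical p-values have resolution `1 / n_perm`; with the default 1000
  shuffles the smallest nonzero p is 0.001, and `p = 0` means "larger
  than every null draw", not a literal zero.
* The Wilcoxon exact path enumerates `choose(n, m)` assignments; the
  10,000-assignment ceiling keeps it to small groups by design.
* Subunit complexes, trimean-style score variants and spatial constraints
  on interactions are out of scope.
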