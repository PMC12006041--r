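---
title: "Clonal barcode mapping of sorted T helper subsets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal barcode mapping of sorted T helper subsets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrtrack)
```

## The model

Every αβ T cell carries a clone-specific TCR rearrangement; within a clone
the CDR3 nucleotide sequence is inherited unchanged. The package treats that
sequence as a barcode linking two experiments performed on the same donor:
deep bulk TCR sequencing of FACS-sorted T helper subsets, and paired
scRNA-Seq/scTCR-Seq of single cells. A cell belongs to sorted subset $j$ if
its resolved TCRβ CDR3 is *identical* to a clonotype in subset $j$'s
selected list from the same donor. Two assumptions drive the design:

1. **Program stability.** A clone sorted into a subset expresses that
   subset's transcriptional program whenever it is sampled again, so the
   clone's cells concentrate in few transcriptome clusters. The method
   measures this concentration rather than assuming it.
2. **Clonality.** A clone must be large enough to be captured in both the
   sorted bulk repertoire and the single-cell run. Selecting the top-$n$
   clonotypes per subset both enforces this and trims minor
   cross-contamination from sorting, at the cost of ignoring small clones —
   subsets as diverse as naive cells are outside the method's reach.

### Mapping accuracy

For subset $j$ with matched-cell distribution $p_{ij}$ over clusters $i$,

$$S_j = -\frac{\sum_{i:\,p_{ij}>0} p_{ij}\,\ln p_{ij}}{\ln N_j},
\qquad N_j = \#\{i : p_{ij} > 0\},$$

the Shannon entropy normalized by its maximum on the occupied clusters.
$S_j \in [0, 1]$; lower is more focused. Conventions: the index is written
with an explicit minus sign so the bounds hold; when $N_j = 1$ the
normalizer vanishes and we define $S_j = 0$ — the maximally focused case by
continuity; terms with $p_{ij} = 0$ contribute nothing; the log base
cancels in the ratio (natural log is used); subsets with fewer than
`min_cells = 8` cells are reported as undefined rather than zero-padded.
Both annotation arms (clonotype matching and CITE-Seq gating) compute
$S_j$ through the same routine (`shannon_by_subset()`) on the same
subsampled universe of annotated cells, so their values are directly
comparable.

### Repertoire statistics

Cluster clonality is the unique-CDR3/cell-count ratio per donor per
cluster. Pairwise clonal overlap between cluster repertoires $A$, $B$ of
one donor is $D = |A \cap B| / (|A|\,|B|)$, displayed as
$\log_2(1 + 10^6 D)$; the diagonal (self-overlap, $1/|A|$) is computed but
excluded from heatmaps since it is a clonality proxy. Donor matrices are
aggregated by the mean over donors in which a pair is defined (median and
sum are available); the aggregator is recorded in the output because the
choice is a convention, not a derivation.

The shared-clonotype partition intersects the top-2,000 clonotype sets of
two sorted subsets and keeps a shared clonotype only when the standard
deviation of its two whole-repertoire frequencies is below 0.001. With two
observations the sample convention gives $sd = |f_A - f_B|/\sqrt{2}$; we
default to it ("standard deviation" of two values most commonly means the
$n-1$ form) and expose the population convention ($|f_A - f_B|/2$) behind
`sd_convention` so the sensitivity of any conclusion to that reading can be
checked directly.

### CITE-Seq comparator

ADT counts are CLR-normalized: for a vector $x$ of length $L$,
$\mathrm{clr}_i = \ln(1 + x_i/g)$ with
$g = \exp\!\big(\sum_{x_j>0}\ln x_j / L\big)$ — the geometric mean over the
full length including zeros, so zero entries map to zero and an all-zero
vector stays zero. The margin is configurable (`per_cell` across the
panel, the default, or `per_marker` across cells, optionally within
batches) because common usage is ambiguous on this point; the choice is
recorded in the normalization metadata.

Gating is sequential: Treg (CD25 above, CD127 below) is consumed first,
then Tfh (CXCR5+ CCR10−), Th22 (CCR10+ CXCR5−), and the chemokine-receptor
splits Th1, Th1-17, Th17, Th2a, Th2 on CCR6/CXCR3/CCR4/CRTh2. The
hierarchy is reconstructed from the classic sort gates and fully
overridable through a YAML gate-spec file; an optional leading
effector/memory node (NOT CCR7+CD45RA+) is off by default because typical
inputs are already memory-sorted. Comparisons are strict (`above`: $x > t$;
`below`: $x < t$), so a value exactly at a threshold satisfies neither
direction — a deterministic, documented tie-break. Thresholds are chosen by
minimizing the mean defined $S_j$ over the gated subsets, by exhaustive
search over the Cartesian product of per-marker candidate grids (ties keep
the first minimum in grid order, making reruns identical); coordinate
descent is available for large grids with the caveat that it may stop in a
local minimum.

### Accuracy comparison

Per-group Shannon values of the two arms are compared with a two-sided
rank-sum test. For small samples the exact permutation distribution of the
rank sum is enumerated — this handles ties correctly, including fully tied
data where the p-value is 1, which the normal-approximation path cannot
represent; larger samples fall back to `stats::wilcox.test`.

## The synthetic-data generator

The generator is first-class, tested code: it produces ground-truth studies
with the statistical structure the method assumes, in exactly the file
dialects the readers consume, so every pipeline stage is testable without
external data. It emulates:

- **Donor-structured clonal repertoires.** Per donor and subset, clones
  with unique in-frame CDR3s (36–54 nt, multiples of 3, no stop codon) and
  sizes following a discrete power law with exponent 2.5 (truncated at the
  clone budget) — the heavy-tailed clonality the method relies on.
  Cross-donor CDR3 collisions default to zero but are injectable to test
  donor scoping.
- **Subset programs.** Each subset concentrates probability 0.85 on its
  own cluster, the remainder uniform over the other 15 — stable clonal
  programs with realistic leakage.
- **Sorting impurity.** A routing matrix sends clones of one subset into
  another subset's tube with a configured probability, carrying the full
  clone size (an impurity moves cells of a clone, not a fraction of its
  reads); the reference impurity scenario routes 40% of Th22 clones into
  the Th17 tube, reproducing the situation where a sorted "Th17" tube is a
  mixture of bona fide Th17 cells and CCR10-low Th22 cells.
- **Single-cell capture.** Cells sample clones size-weighted, draw a
  cluster from their clone's program, and emit 10x-dialect contigs at a
  configurable capture rate; a fraction of cells receives a second, lower-
  UMI decoy contig to exercise most-abundant-chain resolution.
- **Noisy ADT.** Negative-binomial marker counts with subset-dependent
  means encoding the sorting phenotypes, configurable dispersion (`Inf`
  gives the Poisson limit) and per-batch multipliers.

What it does **not** emulate: transcriptome counts (clusters are labels, by
design — clustering is out of scope), cell doublets, ambient contamination,
batch structure in the clonal data, or clones genuinely spanning multiple
programs. Passing the end-to-end tests therefore shows the machinery is
correct under the stated model, not that real sorted subsets are this
clean.

## Problem sizes and study conditions

Fixed once, as the package's reference conditions: 3 donors × 2,000 cells,
8 subsets × 800 clones per donor, bulk depth 30,000 reads per tube,
capture rate 0.95, decoy fraction 0.1, top-500 selection, 20,000-cell
subsampling cap, `min_cells = 8`. The comparator study uses 20 replicates
of a smaller problem (2 donors × 600 cells, 300 clones per subset) under a
high-noise ADT panel (positive mean 25 vs negative mean 12, NB size 0.4) —
marker distributions that overlap heavily, the regime in which clonal
barcodes should outperform surface gating. `scripts/acceptance.R`
recomputes all headline quantities from these conditions at any seed.

## Numerical and degenerate-input choices

- Clonotype sorting ties (equal counts) break by lexicographic CDR3, so
  top-$n$ slices and rank windows are reproducible across input orders.
- Chain resolution ties (equal UMI counts) keep the lexicographically
  smallest CDR3.
- Duplicate clonotype rows merge by summing counts; frequencies are then
  recomputed from counts where counts exist.
- Selected top-$n$ frequencies keep their whole-repertoire values (they are
  per-cell plotting weights), hence a rank-window slice sums below 1.
- Cells matching several subsets stay in all of them — the subsets are
  displayed independently — with `best_subset_per_cell()` for users needing
  a unique assignment.
- Pooled-donor mapping is the default (per-donor runs are a matter of
  filtering the inputs); cluster sizes for the intensity matrix are
  computed on the same subsampled universe as the counts.
- Empty inputs degrade explicitly: empty repertoires warn, empty clusters
  are undefined (never zero) in clonality and overlap, all-zero ADT panels
  normalize to zero with a warning.

## Limitations

The method annotates only populations definable by sorting, only for
lymphocytes with clonal receptors, and only for clones large enough to be
seen twice; diverse compartments (naive, central memory, circulating Tfh)
need much deeper sampling. Matching is exact — no Hamming-neighborhood
rescue — so sequencing errors in CDR3s cost sensitivity, not specificity.
The gating comparator reconstructs a plausible gate hierarchy; a different
antibody panel or hierarchy can change its accuracy, which is why the
hierarchy is a config file rather than a constant.
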