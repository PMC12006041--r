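# tcrtrack

Map phenotypically sorted T helper (Th) cell subsets onto clustered
scRNA-Seq/scTCR-Seq data by using T-cell receptor (TCR) clonotypes as
natural clonal barcodes.

## The problem

Single-cell RNA sequencing resolves CD4+ T helper cells into transcriptome
clusters, but the correspondence between those clusters and the classically
sorted Th subsets (Th1, Th1-17, Th17, Th22, Th2, Th2a, Tfh, Treg — defined by
surface markers such as CD25, CD127, CXCR5, CXCR3, CCR6, CCR4, CRTh2 and
CCR10) is ambiguous: the mRNAs of those markers are often barely detectable,
and antibody-based CITE-Seq gating is noisy. Because each T-cell clone
carries a unique, heritable TCR rearrangement, the bulk TCR repertoire of a
FACS-sorted subset can instead be matched — clone by clone, within each
donor — to the single-cell clonotypes, positioning the sorted subset on the
transcriptome landscape with no reliance on per-cell marker measurements.

## The method

For each donor and sorted subset, the top *n* (default 500) clonotypes of
the subset's bulk TCRβ repertoire are selected by read count. A single cell
is assigned to a subset when its resolved TCRβ CDR3 nucleotide sequence is
identical to a clonotype in that subset's list *from the same donor*
(V/J-augmented matching is optional). For each subset *j* the distribution
`p_ij` of its matched cells across transcriptome clusters *i* yields the
normalized Shannon–Wiener mapping accuracy

    S_j = − Σ_i p_ij · ln(p_ij) / ln(N_j),   N_j = #{i : p_ij > 0}

with `S_j = 0` for a perfectly focused mapping (one occupied cluster) and
`S_j = 1` for a uniform spread; subsets with fewer than 8 matched cells are
excluded. Around this core the package provides:

- **Cluster repertoire statistics** — per-cluster clonality (unique
  CDR3/cell-count ratio) and pairwise clonal overlap
  `D = |A ∩ B| / (|A| · |B|)`, reported as `log2(1 + 10^6 · D)`.
- **Shared-clonotype partition** — overlap of two sorted subsets' top-2,000
  clonotype sets, keeping a shared clonotype only when the standard
  deviation of its two frequencies (`|f_A − f_B| / √2`) is below 0.001;
  this separates clones genuinely spanning both tubes from sorting
  cross-contamination, e.g. CCR10-low Th22 cells inside a sorted Th17 tube.
- **CITE-Seq comparator** — CLR normalization of ADT counts, a sequential
  in-silico gating hierarchy over the eight sorting markers, and gate
  thresholds optimized by minimizing the mean normalized Shannon index;
  accuracy of the two annotation arms is compared with an exact rank-sum
  test.
- **Synthetic-data generator** — donor-structured clonal repertoires with
  power-law clone sizes, subset-specific cluster programs, sorting
  impurity, single-cell capture and noisy ADT counts, emitting exactly the
  file dialects the readers consume (VDJtools-style clonotype TSV, 10x
  `filtered_contig_annotations.csv`, cell metadata TSV, dense or
  MatrixMarket ADT).

## Worked example

```r
library(tcrtrack)

cfg <- synthetic_config(n_donors = 2, cells_per_donor = 400,
                        clones_per_subset = 120, seed = 7)
sim <- simulate_study(cfg)

cells    <- resolve_cell_chains(filter_contigs(sim$contig_records))
selected <- lapply(sim$bulk, select_top_clonotypes, n = 500)
matches  <- match_cells(selected, cells, chain = "TRB")
mapping  <- compute_mapping_matrices(matches, sim$meta, seed = 1)
mapping
#> mapping_result: 8 subsets x 16 clusters, 760 of 760 annotated cells used
#>   subset n_cells n_clusters   shannon defined
#> 1    Tfh     102         10 0.2992667    TRUE
#> 2    Th1      84          9 0.2758632    TRUE
#> 3 Th1-17     91         10 0.3394425    TRUE
#> 4   Th17      84          9 0.3153341    TRUE
#> 5    Th2      76         11 0.4844344    TRUE
#> 6   Th22      99          7 0.2162321    TRUE
#> 7   Th2a     109         13 0.3567194    TRUE
#> 8   Treg     115         11 0.2375907    TRUE
```

760 single cells carried a clonotype found in a sorted subset's top-500
list. Every per-subset Shannon index is low (0.22–0.48): each sorted
subset's clones concentrate on few clusters. The `size` matrix gives each
subset's distribution over clusters — here 92% of the matched Th22 cells sit
in the Th22 cluster:

```r
round(mapping$size["Th22", c("Th22", "Th2", "Th17")], 3)
#>  Th22   Th2  Th17
#> 0.919 0.000 0.000
```

`write_mapping_report(mapping, matches, "out/")` serializes the count,
intensity (stained proportion of each cluster) and size matrices, the
Shannon table and the per-cell matches. The same pipeline is available from
the shell via `inst/cli/tcrtrack` (`simulate`, `map`, `clonality`,
`overlap`, `shared`, `gate` subcommands).

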