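#' Reference label sets
#'
#' Convenience vocabularies for peripheral-blood CD4+ T helper work: the 16
#' transcriptome cluster labels of the integrated Th reference map and the 8
#' classically sorted subset labels. Cluster labels are free strings
#' everywhere in the package; these constants are a convenience, not an
#' enforced vocabulary.
#'
#' @return A character vector of labels.
#' @export
th_cluster_labels <- function() {
  c("Th1", "Th1-17", "Th17", "Th22", "Th2", "Th2a", "Tfh", "Treg",
    "Temra cytotoxic", "Central memory 1", "Central memory 2",
    "Naive", "Naive RTE", "Naive IFN-induced", "Eff-mem IFN-induced",
    "Cycling")
}

#' @rdname th_cluster_labels
#' @export
th_subset_labels <- function() {
  c("Th1", "Th1-17", "Th17", "Th22", "Th2", "Th2a", "Tfh", "Treg")
}

# Surface markers used by the default in-silico gating hierarchy.
.gating_markers <- c("CD25", "CD127", "CXCR5", "CXCR3", "CCR6", "CCR4",
                     "CRTh2", "CCR10")
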