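# Turning a match table plus cluster labels into mapping matrices and the
# normalized Shannon-Wiener accuracy index.

#' Normalized Shannon-Wiener mapping accuracy
#'
#' Quantifies how focused a subset's positioning is across transcriptome
#' clusters: \eqn{S = -\sum_{i: p_i>0} p_i \ln p_i / \ln N}, where `p` is the
#' subset's distribution over clusters and `N` the number of clusters with
#' non-zero hits. `S = 0` is maximal focus (a single occupied cluster, where
#' the normalization itself degenerates); `S = 1` is a uniform spread over the
#' occupied clusters. The lower the value, the more focused the mapping. The
#' log base cancels in the ratio, so any base gives the same value; natural
#' log is used. Subsets with fewer than `min_cells` cells (default 8, i.e.
#' "more than seven") are not evaluated and return `NA`.
#'
#' @param p non-negative proportions over clusters, summing to 1 (zeros
#'   allowed and contributing nothing).
#' @param n_cells number of cells behind `p`, checked against `min_cells`;
#'   `NULL` skips the check.
#' @param min_cells minimum cells for the index to be defined.
#' @param tol tolerance on `sum(p) == 1`.
#' @return A single value in \eqn{[0, 1]}, or `NA` when not defined.
#' @export
shannon_accuracy <- function(p, n_cells = NULL, min_cells = 8L, tol = 1e-6) {
  stopifnot(is.numeric(p), min_cells >= 1L)
  if (any(p < 0)) stop("negative proportion")
  s <- sum(p)
  if (s == 0) return(NA_real_)
  if (abs(s - 1) > tol) {
    stop("proportions sum to ", format(s), ", not 1")
  }
  if (!is.null(n_cells) && n_cells < min_cells) return(NA_real_)
  pos <- p[p > 0]
  n_occ <- length(pos)
  if (n_occ == 1L) return(0)
  -sum(pos * log(pos)) / log(n_occ)
}

# Per-subset Shannon table from a subset x cluster count matrix. Both the
# clonotype-matching arm and the CITE-Seq gating arm compute their accuracy
# through this one routine, so the two methods are directly comparable.
.shannon_from_counts <- function(counts, min_cells = 8L) {
  n_cells <- rowSums(counts)
  s <- vapply(seq_len(nrow(counts)), function(j) {
    if (n_cells[j] == 0) return(NA_real_)
    shannon_accuracy(counts[j, ] / n_cells[j], n_cells = n_cells[j],
                     min_cells = min_cells)
  }, numeric(1L))
  data.frame(subset = rownames(counts),
             n_cells = as.integer(n_cells),
             n_clusters = as.integer(rowSums(counts > 0)),
             shannon = s,
             defined = !is.na(s),
             stringsAsFactors = FALSE)
}

#' Per-subset Shannon accuracy from per-cell labels
#'
#' Convenience wrapper shared by the mapping and gating arms: tabulates
#' subset x cluster counts from parallel per-cell vectors and evaluates
#' [shannon_accuracy()] per subset.
#'
#' @param subset,cluster parallel character vectors (one entry per cell
#'   annotation; cells labeled `"ungated"` are dropped).
#' @param min_cells see [shannon_accuracy()].
#' @return data.frame: `subset`, `n_cells`, `n_clusters`, `shannon`,
#'   `defined`.
#' @export
shannon_by_subset <- function(subset, cluster, min_cells = 8L) {
  keep <- subset != "ungated"
  counts <- table(factor(subset[keep]), factor(cluster[keep]))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  .shannon_from_counts(counts, min_cells = min_cells)
}

#' Subsample annotated cells
#'
#' Draws a uniform random sample, without replacement, among the cells that
#' carry the relevant annotation (matched by clonotype, or gated by surface
#' markers), so the two arms are normalized to the same universe size. Keys
#' are sorted before sampling, making the draw reproducible regardless of
#' input order. If fewer than `n` cells are available, all are used with a
#' warning.
#'
#' @param keys character vector of cell keys (see [cell_key()]); duplicates
#'   are collapsed.
#' @param n sample size (default 20000).
#' @param seed RNG seed; mandatory when an actual draw happens.
#' @return Sorted character vector of sampled keys.
#' @export
subsample_matched_cells <- function(keys, n = 20000L, seed = NULL) {
  stopifnot(n >= 1L)
  keys <- sort(unique(keys))
  if (length(keys) <= n) {
    if (length(keys) < n) {
      warning(sprintf("only %d annotated cells available (< %d): using all",
                      length(keys), n))
    }
    return(keys)
  }
  if (is.null(seed)) stop("seed is required to subsample ", length(keys),
                          " cells down to ", n)
  sort(.with_seed(seed, sample(keys, n)))
}

#' Compute the subset x cluster mapping matrices
#'
#' From a match table and per-cell cluster labels, computes — on a common
#' subsampled universe of annotated cells — the three matrices behind the
#' dot-plot display: `counts` (n_ij, cells of subset j in cluster i),
#' `intensity` (n_ij divided by the cluster's size in the universe: the
#' stained proportion of the cluster) and `size` (n_ij divided by the
#' subset's total: the subset's distribution over clusters), plus the
#' per-subset Shannon accuracy. Cells matched to multiple subsets contribute
#' to each subset's row independently.
#'
#' @param match_table output of [match_cells()] (or any data.frame with
#'   `donor_id`, `barcode`, `subset_label`).
#' @param meta cell metadata from [read_cluster_assignments()].
#' @param subsets,clusters optional label vectors fixing row/column order
#'   (defaults: sorted unique labels observed).
#' @param subsample_n,seed see [subsample_matched_cells()].
#' @param min_cells see [shannon_accuracy()].
#' @return A `mapping_result`: list with `subsets`, `clusters`, `counts`,
#'   `intensity`, `size` (matrices, subsets x clusters), `shannon`
#'   (data.frame) and `subsample` (record of the universe used).
#' @export
compute_mapping_matrices <- function(match_table, meta, subsets = NULL,
                                     clusters = NULL, subsample_n = 20000L,
                                     seed = NULL, min_cells = 8L) {
  mt <- as.data.frame(match_table, stringsAsFactors = FALSE)
  meta_key <- cell_key(meta$donor_id, meta$barcode)
  mt_key <- cell_key(mt$donor_id, mt$barcode)
  pos <- match(mt_key, meta_key)
  if (anyNA(pos)) {
    stop("integrity error: matched cell(s) without a cluster label: ",
         paste(utils::head(mt$barcode[is.na(pos)], 5L), collapse = ", "),
         call. = FALSE)
  }
  mt$cluster_id <- meta$cluster_id[pos]

  universe <- subsample_matched_cells(mt_key, n = subsample_n, seed = seed)
  in_universe <- mt_key %in% universe
  mts <- mt[in_universe, , drop = FALSE]

  if (is.null(subsets)) subsets <- sort(unique(mt$subset_label))
  if (is.null(clusters)) clusters <- sort(unique(meta$cluster_id))

  counts <- table(factor(mts$subset_label, levels = subsets),
                  factor(mts$cluster_id, levels = clusters))
  counts <- matrix(as.integer(counts), nrow = length(subsets),
                   dimnames = list(subsets, clusters))

  cluster_sizes <- table(factor(meta$cluster_id[meta_key %in% universe],
                                levels = clusters))
  cluster_sizes <- as.integer(cluster_sizes)
  denom_i <- ifelse(cluster_sizes > 0, cluster_sizes, 1L)
  intensity <- sweep(counts, 2L, denom_i, "/")
  subset_totals <- rowSums(counts)
  denom_j <- ifelse(subset_totals > 0, subset_totals, 1)
  size <- sweep(counts, 1L, denom_j, "/")

  structure(list(subsets = subsets,
                 clusters = clusters,
                 counts = counts,
                 intensity = intensity,
                 size = size,
                 cluster_sizes = stats::setNames(cluster_sizes, clusters),
                 shannon = .shannon_from_counts(counts, min_cells = min_cells),
                 subsample = list(n = subsample_n, seed = seed,
                                  n_available = length(unique(mt_key)),
                                  n_used = length(universe))),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("mapping_result: %d subsets x %d clusters, %d of %d annotated cells used\n",
              length(x$subsets), length(x$clusters),
              x$subsample$n_used, x$subsample$n_available))
  print(x$shannon, ...)
  invisible(x)
}

# Exact two-sided permutation rank-sum p-value (enumeration over all
# assignments of the pooled ranks to group A).
.exact_ranksum_p <- function(a, b) {
  r <- rank(c(a, b))
  n <- length(a)
  obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(r), n)
  w <- colSums(matrix(r[combos], nrow = n))
  mu <- n * (length(r) + 1) / 2
  mean(abs(w - mu) >= abs(obs - mu) - 1e-9)
}

#' Compare mapping accuracies of two methods
#'
#' Two-sided rank-sum comparison of the defined per-subset (per-group)
#' Shannon values of two annotation methods. For small samples the exact
#' permutation distribution of the rank sum is enumerated, which handles ties
#' (including fully tied data, where p = 1); larger samples fall back to the
#' normal approximation of [stats::wilcox.test()].
#'
#' @param s_a,s_b numeric vectors of Shannon values (NAs = undefined subsets,
#'   dropped).
#' @param exact_limit enumerate the exact distribution when
#'   `choose(n_a + n_b, n_a)` is at most this (default 100000).
#' @return list: per-method `n` and `median`, `statistic` (rank sum of the
#'   first method), `p_value`, `method`, and `low_n` flag (fewer than 3
#'   defined values on either side).
#' @export
compare_accuracy <- function(s_a, s_b, exact_limit = 1e5) {
  a <- s_a[!is.na(s_a)]
  b <- s_b[!is.na(s_b)]
  if (!length(a) || !length(b)) {
    stop("all accuracy values undefined on one side")
  }
  w_stat <- sum(rank(c(a, b))[seq_along(a)])
  if (choose(length(a) + length(b), length(a)) <= exact_limit) {
    p <- .exact_ranksum_p(a, b)
    method <- "exact permutation rank-sum"
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    method <- "Wilcoxon rank-sum (normal approximation)"
  }
  list(n_a = length(a), n_b = length(b),
       median_a = stats::median(a), median_b = stats::median(b),
       statistic = w_stat, p_value = p, method = method,
       low_n = min(length(a), length(b)) < 3L)
}
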