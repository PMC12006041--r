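# Cluster-level repertoire statistics: clonality, pairwise clonal overlap
# (D metric, scaled and log-transformed), and the SD-filtered
# shared-clonotype partition used to disentangle mixed sorted subsets.

#' Cluster repertoire
#'
#' The set of clonotypes (nucleotide CDR3 keys from resolved cells) observed
#' in one transcriptome cluster of one donor, with the number of cells that
#' contributed.
#'
#' @param donor_id,cluster_id identity of the repertoire.
#' @param clonotypes character vector of CDR3 nucleotide sequences (one entry
#'   per cell; duplicates encode clonal expansion).
#' @param cell_count number of cells with a resolved chain in the cluster
#'   (defaults to `length(clonotypes)`).
#' @return A `cluster_repertoire` (list).
#' @export
cluster_repertoire <- function(donor_id, cluster_id, clonotypes,
                               cell_count = length(clonotypes)) {
  stopifnot(length(unique(clonotypes)) <= cell_count)
  structure(list(donor_id = as.character(donor_id),
                 cluster_id = as.character(cluster_id),
                 clonotypes = as.character(clonotypes),
                 cell_count = as.integer(cell_count)),
            class = "cluster_repertoire")
}

#' Build per-donor, per-cluster repertoires from resolved cells
#'
#' @param cells resolved cell chains ([resolve_cell_chains()]).
#' @param meta cell metadata with cluster labels.
#' @param chain chain whose CDR3 defines the clonotype key (TRB default).
#' @return Named list of [cluster_repertoire()]s, keyed `"donor|cluster"`.
#' @export
build_cluster_repertoires <- function(cells, meta, chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  cc <- cells[cells$chain == chain, , drop = FALSE]
  pos <- match(cell_key(cc$donor_id, cc$barcode),
               cell_key(meta$donor_id, meta$barcode))
  if (anyNA(pos)) {
    stop("integrity error: resolved cell(s) without a cluster label",
         call. = FALSE)
  }
  cc$cluster_id <- meta$cluster_id[pos]
  groups <- split(cc$cdr3nt, list(cc$donor_id, cc$cluster_id), drop = TRUE,
                  sep = "|")
  reps <- lapply(sort(names(groups)), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    cluster_repertoire(parts[1L], paste(parts[-1L], collapse = "|"),
                       groups[[k]])
  })
  stats::setNames(reps, sort(names(groups)))
}

#' Cluster clonality ratio
#'
#' Unique CDR3 count divided by cell count, computed per donor per cluster.
#' A ratio of 1 means every cell carries a distinct clonotype; lower values
#' indicate clonal expansion. Empty clusters are not defined (`NA`).
#'
#' @param rep a [cluster_repertoire()].
#' @return Ratio in (0, 1], or `NA` for an empty cluster.
#' @export
cluster_clonality <- function(rep) {
  if (rep$cell_count == 0L) return(NA_real_)
  length(unique(rep$clonotypes)) / rep$cell_count
}

#' Pairwise clonal overlap (D metric)
#'
#' The number of clonotypes shared between two cluster repertoires of the
#' same donor divided by the product of their unique clonotype counts:
#' \eqn{D = |A \cap B| / (|A| \cdot |B|)}. For display the value is
#' multiplied by a scale factor (default 1e6) and log2(1 + x) transformed.
#'
#' @param rep_a,rep_b [cluster_repertoire()]s from the same donor.
#' @param scale multiplier applied before the log transform.
#' @return list with `D` (raw) and `transformed`; both `NA` when either
#'   clonotype set is empty.
#' @export
pairwise_overlap_D <- function(rep_a, rep_b, scale = 1e6) {
  if (rep_a$donor_id != rep_b$donor_id) {
    stop("overlap is donor-scoped: ", rep_a$donor_id, " vs ", rep_b$donor_id)
  }
  a <- unique(rep_a$clonotypes)
  b <- unique(rep_b$clonotypes)
  if (!length(a) || !length(b)) {
    return(list(D = NA_real_, transformed = NA_real_))
  }
  d <- length(intersect(a, b)) / (length(a) * length(b))
  list(D = d, transformed = log2(1 + scale * d))
}

#' All-pairs overlap matrix for one donor
#'
#' @param reps list of [cluster_repertoire()]s, all from one donor.
#' @param scale see [pairwise_overlap_D()].
#' @return list: `donor_id`, `clusters`, symmetric matrices `D` and
#'   `transformed` (diagonal = self-overlap, reported but conventionally
#'   excluded from heatmaps as a clonality proxy).
#' @export
donor_overlap_matrix <- function(reps, scale = 1e6) {
  donors <- unique(vapply(reps, `[[`, character(1L), "donor_id"))
  if (length(donors) != 1L) stop("repertoires from multiple donors: ",
                                 paste(donors, collapse = ", "))
  clusters <- vapply(reps, `[[`, character(1L), "cluster_id")
  k <- length(reps)
  d <- tr <- matrix(NA_real_, k, k, dimnames = list(clusters, clusters))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ov <- pairwise_overlap_D(reps[[i]], reps[[j]], scale = scale)
      d[i, j] <- d[j, i] <- ov$D
      tr[i, j] <- tr[j, i] <- ov$transformed
    }
  }
  list(donor_id = donors, clusters = clusters, D = d, transformed = tr,
       scale = scale)
}

#' Aggregate per-donor overlap matrices
#'
#' Cluster pairs are aggregated as the mean over the donors in which the pair
#' is defined (both repertoires non-empty); `"sum"` and `"median"` are
#' available as alternatives. The per-pair donor count is reported alongside.
#'
#' @param donor_matrices list of [donor_overlap_matrix()] results.
#' @param aggregator `"mean"` (default), `"median"` or `"sum"`.
#' @return list: `aggregate` (cluster x cluster matrix, `NA` where no donor
#'   defines the pair), `n_donors` (integer matrix), `aggregator`,
#'   `per_donor`.
#' @export
aggregate_overlap <- function(donor_matrices,
                              aggregator = c("mean", "median", "sum")) {
  aggregator <- match.arg(aggregator)
  stopifnot(length(donor_matrices) >= 1L)
  clusters <- sort(unique(unlist(lapply(donor_matrices, `[[`, "clusters"))))
  k <- length(clusters)
  stack <- vapply(donor_matrices, function(m) {
    full <- matrix(NA_real_, k, k, dimnames = list(clusters, clusters))
    full[m$clusters, m$clusters] <- m$transformed
    full
  }, matrix(numeric(1L), k, k))
  dim(stack) <- c(k, k, length(donor_matrices))
  fun <- switch(aggregator, mean = mean, median = stats::median, sum = sum)
  agg <- apply(stack, c(1L, 2L), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else fun(v)
  })
  n <- apply(stack, c(1L, 2L), function(v) sum(!is.na(v)))
  dimnames(agg) <- dimnames(n) <- list(clusters, clusters)
  list(aggregate = agg, n_donors = n, aggregator = aggregator,
       per_donor = donor_matrices)
}

#' Partition the shared clonotypes of two sorted-subset repertoires
#'
#' Overlap is computed on nucleotide CDR3 identity within the two top-`n`
#' slices. For each overlapping clonotype the standard deviation of its two
#' whole-repertoire frequencies is evaluated — sample convention
#' \eqn{sd = |f_A - f_B| / \sqrt{2}} by default (population convention
#' \eqn{|f_A - f_B| / 2} behind the flag) — and the clonotype is kept as
#' genuinely shared iff `sd < sd_threshold`. This excludes clonotypes that
#' are highly abundant in one subset but only marginally present in the
#' other, i.e. likely sorting cross-contamination rather than a clone truly
#' spanning both tubes. Non-overlapping clonotypes go to `a_only` / `b_only`.
#'
#' @param rep_a,rep_b [bulk_repertoire()]s from the same donor (frequencies
#'   must be whole-repertoire fractions).
#' @param top_n slice size (default 2000).
#' @param sd_threshold keep threshold on the two-frequency SD (default 0.001).
#' @param sd_convention `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return A `shared_partition`: list with clonotype sets `a_only`, `b_only`,
#'   `shared_kept`, `shared_rejected`, a per-overlapping-clonotype `records`
#'   data.frame (`cdr3nt`, `freq_a`, `freq_b`, `sd`, `kept`) and `params`.
#' @export
shared_clonotype_partition <- function(rep_a, rep_b, top_n = 2000L,
                                       sd_threshold = 0.001,
                                       sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (!identical(attr(rep_a, "donor_id"), attr(rep_b, "donor_id"))) {
    stop("shared-clonotype partition is donor-scoped")
  }
  slice_freq <- function(rep) {
    top <- select_top_clonotypes(rep, n = top_n)
    # partition on nucleotide identity: collapse V/J-split rows
    v <- as.vector(rowsum(top$frequency, top$cdr3nt))
    stats::setNames(v, sort(unique(top$cdr3nt)))
  }
  fa <- slice_freq(rep_a)
  fb <- slice_freq(rep_b)
  shared <- intersect(names(fa), names(fb))
  denom <- if (sd_convention == "sample") sqrt(2) else 2
  sdv <- abs(fa[shared] - fb[shared]) / denom
  kept <- sdv < sd_threshold
  records <- data.frame(cdr3nt = shared,
                        freq_a = unname(fa[shared]),
                        freq_b = unname(fb[shared]),
                        sd = unname(sdv),
                        kept = unname(kept),
                        stringsAsFactors = FALSE)
  records <- records[order(records$cdr3nt), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(a_only = setdiff(names(fa), shared),
                 b_only = setdiff(names(fb), shared),
                 shared_kept = shared[kept],
                 shared_rejected = shared[!kept],
                 records = records,
                 params = list(top_n = top_n, sd_threshold = sd_threshold,
                               sd_convention = sd_convention)),
            class = "shared_partition")
}
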