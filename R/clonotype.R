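# The barcode machinery: contig QC, per-cell chain resolution, top-N
# clonotype selection, and donor-scoped exact clonotype matching.

#' Quality-filter single-cell contigs
#'
#' Retains only contigs that can serve as clonal barcodes: TRA/TRB chain,
#' productive, full-length (V/J-spanning), with a CDR3 call whose amino-acid
#' sequence contains no stop symbol (`*`).
#'
#' @param contigs contig table from [read_sc_contigs()].
#' @return The filtered contig table.
#' @export
filter_contigs <- function(contigs) {
  keep <- contigs$chain %in% c("TRA", "TRB") &
    contigs$is_productive &
    contigs$is_full_length &
    contigs$has_cdr3 &
    !grepl("*", contigs$cdr3aa, fixed = TRUE)
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve one clonotype per cell per chain
#'
#' Cells frequently carry more than one contig per chain; the most abundant
#' (highest UMI count) contig is kept, with ties broken deterministically by
#' lexicographically smallest CDR3 nucleotide sequence. Input must already be
#' QC-filtered. Cells with no surviving contig simply do not appear here; they
#' stay in cluster-size denominators through the cell metadata table.
#'
#' @param contigs QC-filtered contig table.
#' @return data.frame of resolved cell chains, one row per
#'   (donor, barcode, chain): `donor_id`, `barcode`, `chain`, `cdr3nt`,
#'   `cdr3aa`, `v_gene`, `j_gene`, `umi_count`.
#' @export
resolve_cell_chains <- function(contigs) {
  cols <- c("donor_id", "barcode", "chain", "cdr3nt", "cdr3aa",
            "v_gene", "j_gene", "umi_count")
  if (nrow(contigs) == 0L) {
    out <- contigs[, cols, drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  ord <- order(contigs$donor_id, contigs$barcode, contigs$chain,
               -contigs$umi_count, contigs$cdr3nt, method = "radix")
  x <- contigs[ord, , drop = FALSE]
  first <- !duplicated(x[, c("donor_id", "barcode", "chain")])
  out <- x[first, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the largest clonotypes of a bulk repertoire
#'
#' Clonotypes are ranked by count (descending; ties broken by lexicographic
#' `cdr3nt`) and sliced to the top `n`, or to an inclusive 1-based rank window
#' (e.g. `c(101, 500)` for the 101st-500th largest). Frequencies keep their
#' original whole-repertoire values — they are used downstream as per-cell
#' weights, not renormalized within the slice.
#'
#' @param rep a [bulk_repertoire()].
#' @param n number of top clonotypes (default 500).
#' @param rank_window optional `c(lo, hi)` rank window; overrides `n`.
#' @return A `bulk_repertoire` with an additional `rank` column.
#' @export
select_top_clonotypes <- function(rep, n = 500L, rank_window = NULL) {
  stopifnot(n >= 1L)
  at <- attributes(rep)
  df <- as.data.frame(rep, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty repertoire: nothing to select")
    df$rank <- integer(0)
  } else {
    sort_key <- if (all(is.na(df$count))) -df$frequency else -df$count
    df <- df[order(sort_key, df$cdr3nt), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    idx <- if (is.null(rank_window)) {
      seq_len(min(n, nrow(df)))
    } else {
      stopifnot(length(rank_window) == 2L, rank_window[1L] >= 1L,
                rank_window[1L] <= rank_window[2L])
      seq(rank_window[1L], rank_window[2L])
    }
    df <- df[idx[idx <= nrow(df)], , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, donor_id = at$donor_id, subset_label = at$subset_label,
            chain = at$chain, class = c("bulk_repertoire", "data.frame"))
}

.match_key_values <- function(cdr3nt, v_gene, j_gene, match_key) {
  if (match_key == "cdr3nt") cdr3nt else paste(cdr3nt, v_gene, j_gene, sep = "\r")
}

#' Match single cells to sorted-subset repertoires
#'
#' The core of the method: a cell is assigned to sorted subset S if and only
#' if its resolved clonotype on the chosen chain is identical — by nucleotide
#' CDR3, optionally augmented with V/J calls — to a clonotype in S's selected
#' list *from the same donor*. All (cell, subset) matches are emitted: a cell
#' whose clonotype sits in several subsets' lists appears once per subset.
#' The lookup is an exact hash join; results are independent of input order.
#'
#' @param subset_reps list of selected [bulk_repertoire()]s (typically the
#'   output of [select_top_clonotypes()], one per donor x subset).
#' @param cells resolved cell chains from [resolve_cell_chains()].
#' @param chain chain to match on (`"TRB"` default).
#' @param match_key `"cdr3nt"` (nucleotide identity, the default) or
#'   `"cdr3nt_vj"` (also requiring identical V and J calls).
#' @return A `match_table` data.frame: `donor_id`, `barcode`, `subset_label`,
#'   `cdr3nt`, `bulk_frequency`, `bulk_rank`.
#' @export
match_cells <- function(subset_reps, cells, chain = c("TRB", "TRA"),
                        match_key = c("cdr3nt", "cdr3nt_vj")) {
  chain <- match.arg(chain)
  match_key <- match.arg(match_key)
  cc <- cells[cells$chain == chain, , drop = FALSE]
  rep_donors <- vapply(subset_reps, attr, character(1L), "donor_id")
  lost <- setdiff(unique(cc$donor_id), rep_donors)
  if (length(lost)) {
    warning("donor(s) with cells but no repertoire: ",
            paste(lost, collapse = ", "))
  }
  rows <- lapply(subset_reps, function(rep) {
    donor <- attr(rep, "donor_id")
    sub <- cc[cc$donor_id == donor, , drop = FALSE]
    if (nrow(sub) == 0L || nrow(rep) == 0L) return(NULL)
    rep_rank <- if ("rank" %in% names(rep)) rep$rank else seq_len(nrow(rep))
    hit <- match(.match_key_values(sub$cdr3nt, sub$v_gene, sub$j_gene, match_key),
                 .match_key_values(rep$cdr3nt, rep$v_gene, rep$j_gene, match_key))
    ok <- !is.na(hit)
    if (!any(ok)) return(NULL)
    data.frame(donor_id = sub$donor_id[ok],
               barcode = sub$barcode[ok],
               subset_label = attr(rep, "subset_label"),
               cdr3nt = sub$cdr3nt[ok],
               bulk_frequency = rep$frequency[hit[ok]],
               bulk_rank = rep_rank[hit[ok]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(donor_id = character(), barcode = character(),
                      subset_label = character(), cdr3nt = character(),
                      bulk_frequency = numeric(), bulk_rank = integer(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$donor_id, out$subset_label, out$barcode, out$cdr3nt), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, chain = chain, match_key = match_key,
            class = c("match_table", "data.frame"))
}

#' Unique best-subset assignment per cell
#'
#' Multi-subset hits are retained in the match table because the subsets are
#' analyzed independently; for users needing a unique per-cell assignment,
#' this picks the subset in which the matched clonotype has the highest bulk
#' frequency (ties broken alphabetically by subset label).
#'
#' @param match_table output of [match_cells()].
#' @return data.frame with one row per matched cell: `donor_id`, `barcode`,
#'   `best_subset`, `bulk_frequency`.
#' @export
best_subset_per_cell <- function(match_table) {
  if (nrow(match_table) == 0L) {
    return(data.frame(donor_id = character(), barcode = character(),
                      best_subset = character(), bulk_frequency = numeric(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(match_table$donor_id, match_table$barcode,
               -match_table$bulk_frequency, match_table$subset_label)
  x <- match_table[ord, , drop = FALSE]
  first <- !duplicated(x[, c("donor_id", "barcode")])
  out <- data.frame(donor_id = x$donor_id[first], barcode = x$barcode[first],
                    best_subset = x$subset_label[first],
                    bulk_frequency = x$bulk_frequency[first],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
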