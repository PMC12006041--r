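# Readers and writers for every external table the tool touches. All dialects
# are normalized into the internal data model here; downstream modules never
# see raw columns.

# Default column synonyms. VDJtools names come first; MiXCR and AIRR
# rearrangement exports are covered by the alternatives. A user `column_map`
# (internal name -> source column) overrides the lookup.
.rep_column_synonyms <- list(
  cdr3nt    = c("cdr3nt", "cdr3_nt", "nSeqCDR3", "junction",
                "CDR3.nucleotide.sequence"),
  cdr3aa    = c("cdr3aa", "cdr3_aa", "aaSeqCDR3", "junction_aa",
                "CDR3.amino.acid.sequence"),
  v_gene    = c("v", "v_gene", "bestVGene", "v_call", "V.gene"),
  j_gene    = c("j", "j_gene", "bestJGene", "j_call", "J.gene"),
  count     = c("count", "#count", "cloneCount", "duplicate_count",
                "Read.count", "reads"),
  frequency = c("freq", "frequency", "cloneFraction", "Percentage")
)

.resolve_column <- function(cols, internal, column_map = NULL) {
  if (!is.null(column_map) && internal %in% names(column_map)) {
    cand <- column_map[[internal]]
    return(if (cand %in% cols) cand else NA_character_)
  }
  hit <- intersect(.rep_column_synonyms[[internal]], cols)
  if (length(hit)) hit[[1L]] else NA_character_
}

#' Construct a bulk repertoire object
#'
#' A bulk repertoire is a clonotype table from deep sequencing of a sorted
#' cell population: one row per rearrangement (CDR3 nucleotide sequence plus
#' optional V/J calls), with a read count and/or a whole-repertoire frequency.
#' Rows sharing the clonotype key `(cdr3nt, v_gene, j_gene)` are merged by
#' summing their abundances, frequencies are recomputed from counts when
#' counts are present, and the table is sorted by abundance (descending,
#' ties broken by `cdr3nt` for determinism).
#'
#' @param clonotypes data.frame with at least `cdr3nt` and one of
#'   `count`/`frequency`; `cdr3aa`, `v_gene`, `j_gene` optional.
#' @param donor_id,subset_label donor and sorted-subset identity of the tube.
#' @param chain `"TRB"` or `"TRA"`.
#' @return A `bulk_repertoire`: a data.frame with columns `cdr3nt`, `cdr3aa`,
#'   `v_gene`, `j_gene`, `count`, `frequency` and attributes `donor_id`,
#'   `subset_label`, `chain`.
#' @export
bulk_repertoire <- function(clonotypes, donor_id, subset_label,
                            chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  df <- as.data.frame(clonotypes, stringsAsFactors = FALSE)
  if (!"cdr3nt" %in% names(df)) .stop_format("clonotype table needs a cdr3nt column")
  for (col in c("cdr3aa", "v_gene", "j_gene")) {
    if (!col %in% names(df)) df[[col]] <- rep("", nrow(df))
    df[[col]][is.na(df[[col]])] <- ""
  }
  has_count <- "count" %in% names(df) && !all(is.na(df$count))
  has_freq <- "frequency" %in% names(df) && !all(is.na(df$frequency))
  if (!has_count && !has_freq && nrow(df) > 0L) {
    .stop_format("clonotype table needs a count or frequency column")
  }
  if (!has_count) df$count <- rep(NA_integer_, nrow(df))
  if (!has_freq) df$frequency <- rep(NA_real_, nrow(df))

  # merge duplicate clonotype keys by summing abundances
  key <- paste(df$cdr3nt, df$v_gene, df$j_gene, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    agg_count <- if (has_count) as.vector(rowsum(as.numeric(df$count), key)) else NULL
    agg_freq <- if (has_freq) as.vector(rowsum(as.numeric(df$frequency), key)) else NULL
    ord_key <- sort(unique(key))
    df <- df[first, , drop = FALSE]
    pos <- match(paste(df$cdr3nt, df$v_gene, df$j_gene, sep = "\r"), ord_key)
    if (has_count) df$count <- agg_count[pos]
    if (has_freq) df$frequency <- agg_freq[pos]
  }
  if (has_count) {
    df$count <- as.integer(round(df$count))
    if (any(df$count < 0)) .stop_format("negative clonotype count")
    total <- sum(df$count)
    if (total > 0) df$frequency <- df$count / total
  }
  sort_key <- if (has_count) -df$count else -df$frequency
  df <- df[order(sort_key, df$cdr3nt), , drop = FALSE]
  df <- df[, c("cdr3nt", "cdr3aa", "v_gene", "j_gene", "count", "frequency")]
  rownames(df) <- NULL
  structure(df,
            donor_id = as.character(donor_id),
            subset_label = as.character(subset_label),
            chain = chain,
            class = c("bulk_repertoire", "data.frame"))
}

#' Read a bulk TCR repertoire table
#'
#' Reads a tab- or comma-separated clonotype table (VDJtools dialect by
#' default; MiXCR/AIRR column names are recognized, and `column_map` handles
#' anything else), drops rows whose CDR3 nucleotide sequence contains
#' characters outside ACGT (with a warning), merges duplicate clonotype keys,
#' recomputes frequencies from counts, and sorts by abundance.
#'
#' @param source path to a delimited file, or a data.frame already in memory.
#' @param donor_id,subset_label,chain repertoire identity (see
#'   [bulk_repertoire()]).
#' @param column_map optional named list mapping internal names (`cdr3nt`,
#'   `cdr3aa`, `v_gene`, `j_gene`, `count`, `frequency`) to source columns.
#' @return A [bulk_repertoire()].
#' @export
read_bulk_repertoire <- function(source, donor_id, subset_label,
                                 chain = c("TRB", "TRA"), column_map = NULL) {
  chain <- match.arg(chain)
  raw <- .read_table_auto(source)
  cols <- names(raw)
  nt_col <- .resolve_column(cols, "cdr3nt", column_map)
  if (is.na(nt_col)) .stop_format("no CDR3 nucleotide column found among: ",
                                  paste(cols, collapse = ", "))
  count_col <- .resolve_column(cols, "count", column_map)
  freq_col <- .resolve_column(cols, "frequency", column_map)
  if (is.na(count_col) && is.na(freq_col)) {
    .stop_format("no abundance column (count or frequency) found")
  }
  pick <- function(internal) {
    col <- .resolve_column(cols, internal, column_map)
    if (is.na(col)) NULL else raw[[col]]
  }
  df <- data.frame(cdr3nt = toupper(as.character(raw[[nt_col]])),
                   stringsAsFactors = FALSE)
  for (col in c("cdr3aa", "v_gene", "j_gene")) {
    v <- pick(col)
    df[[col]] <- if (is.null(v)) "" else as.character(v)
  }
  df$count <- if (is.na(count_col)) NA_integer_ else as.numeric(raw[[count_col]])
  df$frequency <- if (is.na(freq_col)) NA_real_ else as.numeric(raw[[freq_col]])

  bad <- !grepl("^[ACGT]+$", df$cdr3nt)
  if (any(bad)) {
    warning(sprintf("dropped %d clonotype row(s) with non-ACGT CDR3 sequence",
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  bulk_repertoire(df, donor_id, subset_label, chain)
}

#' Write a bulk repertoire as a VDJtools-style TSV
#'
#' @param rep a [bulk_repertoire()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bulk_repertoire <- function(rep, path) {
  df <- data.frame(count = rep$count,
                   freq = .fmt_num(rep$frequency),
                   cdr3nt = rep$cdr3nt, cdr3aa = rep$cdr3aa,
                   v = rep$v_gene, j = rep$j_gene,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 10x filtered_contig_annotations.csv synonyms
.contig_column_synonyms <- list(
  barcode = c("barcode", "cell_id"),
  chain = c("chain", "locus"),
  cdr3nt = c("cdr3_nt", "cdr3nt", "junction"),
  cdr3aa = c("cdr3", "cdr3aa", "junction_aa"),
  v_gene = c("v_gene", "v_call"),
  j_gene = c("j_gene", "j_call"),
  umi_count = c("umis", "umi_count", "duplicate_count"),
  is_productive = c("productive"),
  is_full_length = c("full_length", "complete_vdj")
)

.as_flag <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

#' Read a single-cell contig annotation table
#'
#' Consumes the 10x `filtered_contig_annotations.csv` dialect (or a data.frame
#' in that shape). Boolean-like strings (`"True"`, `"true"`, `"None"`, ...)
#' are normalized to flags; `"None"` and empty CDR3 fields yield
#' `has_cdr3 = FALSE`; chain values other than TRA/TRB are mapped to
#' `"other"` and retained (they are removed later by [filter_contigs()]).
#'
#' @param source path or data.frame.
#' @param donor_id donor the run belongs to (barcodes are donor-scoped).
#' @param column_map optional named list of column overrides.
#' @return data.frame of contig records: `barcode`, `donor_id`, `chain`,
#'   `cdr3nt`, `cdr3aa`, `v_gene`, `j_gene`, `umi_count`, `is_productive`,
#'   `is_full_length`, `has_cdr3`.
#' @export
read_sc_contigs <- function(source, donor_id, column_map = NULL) {
  raw <- .read_table_auto(source)
  empty <- data.frame(barcode = character(), donor_id = character(),
                      chain = character(), cdr3nt = character(),
                      cdr3aa = character(), v_gene = character(),
                      j_gene = character(), umi_count = integer(),
                      is_productive = logical(), is_full_length = logical(),
                      has_cdr3 = logical(), stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty contig table for donor ", donor_id)
    return(empty)
  }
  get_col <- function(internal, required = TRUE) {
    if (!is.null(column_map) && internal %in% names(column_map)) {
      col <- column_map[[internal]]
    } else {
      hit <- intersect(.contig_column_synonyms[[internal]], names(raw))
      col <- if (length(hit)) hit[[1L]] else NA_character_
    }
    if (is.na(col) || !col %in% names(raw)) {
      if (required) .stop_format("contig table lacks a ", internal, " column")
      return(NULL)
    }
    raw[[col]]
  }
  barcode <- as.character(get_col("barcode"))
  if (any(is.na(barcode) | barcode == "")) {
    .stop_format("empty barcode in contig row(s) ",
                 paste(which(is.na(barcode) | barcode == ""), collapse = ","))
  }
  chain <- toupper(as.character(get_col("chain")))
  chain[!chain %in% c("TRA", "TRB")] <- "other"
  cdr3nt <- toupper(as.character(get_col("cdr3nt")))
  cdr3aa <- as.character(get_col("cdr3aa"))
  umi <- suppressWarnings(as.integer(get_col("umi_count")))
  if (any(is.na(umi))) {
    .stop_format("unreadable UMI count in contig row(s) ",
                 paste(which(is.na(umi)), collapse = ","))
  }
  if (any(umi < 0)) .stop_format("negative UMI count")
  has_cdr3 <- !is.na(cdr3nt) & cdr3nt != "" & cdr3nt != "NONE"
  cdr3nt[!has_cdr3] <- ""
  cdr3aa[is.na(cdr3aa) | cdr3aa == "None"] <- ""
  vg <- get_col("v_gene", required = FALSE)
  jg <- get_col("j_gene", required = FALSE)
  data.frame(barcode = barcode,
             donor_id = as.character(donor_id),
             chain = chain,
             cdr3nt = cdr3nt,
             cdr3aa = cdr3aa,
             v_gene = if (is.null(vg)) "" else as.character(vg),
             j_gene = if (is.null(jg)) "" else as.character(jg),
             umi_count = umi,
             is_productive = .as_flag(get_col("is_productive")),
             is_full_length = .as_flag(get_col("is_full_length")),
             has_cdr3 = has_cdr3,
             stringsAsFactors = FALSE)
}

#' Read per-cell cluster assignments
#'
#' @param source path or data.frame with columns `barcode`, `donor_id`,
#'   `cluster_id`. Extra columns are ignored for analysis but preserved in the
#'   `"extras"` attribute.
#' @return data.frame of cell metadata; duplicate `(barcode, donor_id)` pairs
#'   are an integrity error.
#' @export
read_cluster_assignments <- function(source) {
  raw <- .read_table_auto(source)
  need <- c("barcode", "donor_id", "cluster_id")
  missing <- setdiff(need, names(raw))
  if (length(missing)) .stop_format("cell metadata lacks column(s): ",
                                    paste(missing, collapse = ", "))
  meta <- data.frame(barcode = as.character(raw$barcode),
                     donor_id = as.character(raw$donor_id),
                     cluster_id = as.character(raw$cluster_id),
                     stringsAsFactors = FALSE)
  key <- cell_key(meta$donor_id, meta$barcode)
  if (anyDuplicated(key)) {
    stop("integrity error: duplicated (barcode, donor_id) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  extras <- setdiff(names(raw), need)
  if (length(extras)) {
    attr(meta, "extras") <- raw[, extras, drop = FALSE]
  }
  meta
}

#' Read an ADT count matrix
#'
#' Accepts either a dense TSV (first column = cell barcode, remaining columns
#' = markers) or a MatrixMarket triplet file with companion name files
#' (`features` = one marker per line, rows of the sparse matrix; `barcodes` =
#' one cell per line, columns — the 10x orientation). Counts are returned as
#' given; no normalization is applied here.
#'
#' @param source path to the dense TSV or the `.mtx` file.
#' @param features,barcodes name files, required for MatrixMarket input. A
#'   TSV with multiple columns is allowed; the first column is used.
#' @param batch per-cell batch labels: `NULL` (single batch), a single value,
#'   or a vector of length n_cells.
#' @return An `adt_matrix`: list with `counts` (cells x markers), `cells`,
#'   `markers`, `batch`.
#' @export
read_adt_matrix <- function(source, features = NULL, barcodes = NULL,
                            batch = NULL) {
  if (is.character(source) && grepl("\\.mtx$", source)) {
    if (is.null(features) || is.null(barcodes)) {
      .stop_format("MatrixMarket input needs features and barcodes files")
    }
    m <- Matrix::readMM(source)
    feat <- utils::read.delim(features, header = FALSE,
                              stringsAsFactors = FALSE)[[1L]]
    bc <- utils::read.delim(barcodes, header = FALSE,
                            stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) != length(feat) || ncol(m) != length(bc)) {
      .stop_format("matrix dimensions (", nrow(m), "x", ncol(m),
                   ") do not match name files (", length(feat), " features, ",
                   length(bc), " barcodes)")
    }
    counts <- t(as.matrix(m))
    dimnames(counts) <- list(bc, feat)
  } else {
    raw <- .read_table_auto(source)
    if (ncol(raw) < 2L) .stop_format("dense ADT table needs barcode + marker columns")
    counts <- as.matrix(raw[, -1L, drop = FALSE])
    storage.mode(counts) <- "double"
    rownames(counts) <- as.character(raw[[1L]])
  }
  adt_matrix(counts, batch = batch)
}

#' @rdname read_adt_matrix
#' @param counts numeric cells x markers matrix with dimnames.
#' @export
adt_matrix <- function(counts, batch = NULL) {
  if (any(counts < 0)) .stop_format("negative ADT count")
  if (anyDuplicated(colnames(counts))) .stop_format("duplicated marker names")
  n <- nrow(counts)
  if (is.null(batch)) batch <- "batch1"
  if (length(batch) == 1L) batch <- rep(batch, n)
  if (length(batch) != n) .stop_format("batch vector length != number of cells")
  structure(list(counts = counts,
                 cells = rownames(counts),
                 markers = colnames(counts),
                 batch = as.character(batch)),
            class = "adt_matrix")
}

#' Write the mapping report
#'
#' Serializes a [compute_mapping_matrices()] result: subset x cluster TSVs for
#' counts, intensity (stained proportion of each cluster) and size (each
#' subset's distribution over clusters), the per-subset Shannon table, the
#' per-cell match table carrying each matched cell's clonal frequency in the
#' originating bulk repertoire (the per-cell alpha weight used for plotting),
#' and a run-metadata file. All floats use 6 significant digits, so reruns
#' with the same seed are byte-identical.
#'
#' @param result a `mapping_result`.
#' @param match_table the match table the result was computed from.
#' @param out_dir output directory (created if needed).
#' @param params named list recorded in the metadata file.
#' @return Character vector of file paths, invisibly.
#' @export
write_mapping_report <- function(result, match_table, out_dir,
                                 params = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  if (nrow(match_table) == 0L) {
    warning("empty match table: writing header-only report")
  }
  paths <- c(counts = file.path(out_dir, "mapping_counts.tsv"),
             intensity = file.path(out_dir, "mapping_intensity.tsv"),
             size = file.path(out_dir, "mapping_size.tsv"),
             shannon = file.path(out_dir, "shannon.tsv"),
             per_cell = file.path(out_dir, "per_cell_matches.tsv"),
             dot_plot = file.path(out_dir, "dot_plot_long.tsv"),
             metadata = file.path(out_dir, "run_metadata.txt"))
  .write_matrix_tsv(result$counts, paths[["counts"]], label = "subset")
  .write_matrix_tsv(result$intensity, paths[["intensity"]], label = "subset")
  .write_matrix_tsv(result$size, paths[["size"]], label = "subset")
  .write_tsv(result$shannon, paths[["shannon"]])
  .write_tsv(as.data.frame(match_table), paths[["per_cell"]])
  long <- expand.grid(subset = result$subsets, cluster = result$clusters,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$intensity <- as.vector(result$intensity[cbind(long$subset, long$cluster)])
  long$size <- as.vector(result$size[cbind(long$subset, long$cluster)])
  .write_tsv(long, paths[["dot_plot"]])
  meta <- c(sprintf("tcrtrack version: %s",
                    as.character(utils::packageVersion("tcrtrack"))),
            sprintf("subsample_n: %s", result$subsample$n),
            sprintf("subsample_seed: %s",
                    if (is.null(result$subsample$seed)) "NA" else result$subsample$seed),
            sprintf("cells_available: %s", result$subsample$n_available),
            sprintf("cells_used: %s", result$subsample$n_used),
            vapply(names(params), function(k) {
              sprintf("%s: %s", k, paste(params[[k]], collapse = " "))
            }, character(1L)))
  writeLines(meta, paths[["metadata"]])
  invisible(paths)
}
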