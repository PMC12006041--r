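# Fixture builders shared across test files. Everything is generated in code;
# no data files ship with the tests.

random_nt <- function(n, len = 24L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

make_repertoire <- function(cdr3nt, counts, donor = "D01", subset = "Th17",
                            v = NULL, j = NULL, chain = "TRB") {
  n <- length(cdr3nt)
  bulk_repertoire(data.frame(cdr3nt = cdr3nt,
                             cdr3aa = strtrim(cdr3nt, 6L),
                             v_gene = rep_len(if (is.null(v)) "TRBV9" else v, n),
                             j_gene = rep_len(if (is.null(j)) "TRBJ1-1" else j, n),
                             count = counts,
                             stringsAsFactors = FALSE),
                  donor_id = donor, subset_label = subset, chain = chain)
}

make_contigs <- function(barcode, cdr3nt, umis = 5L, chain = "TRB",
                         donor = "D01", cdr3aa = NULL, v = "TRBV9",
                         j = "TRBJ1-1", productive = TRUE, full_length = TRUE) {
  n <- max(length(barcode), length(cdr3nt), length(umis), length(chain))
  data.frame(barcode = rep_len(barcode, n),
             donor_id = rep_len(donor, n),
             chain = rep_len(chain, n),
             cdr3nt = rep_len(cdr3nt, n),
             cdr3aa = rep_len(if (is.null(cdr3aa)) strtrim(cdr3nt, 6L)
                              else cdr3aa, n),
             v_gene = rep_len(v, n),
             j_gene = rep_len(j, n),
             umi_count = as.integer(rep_len(umis, n)),
             is_productive = rep_len(productive, n),
             is_full_length = rep_len(full_length, n),
             has_cdr3 = rep_len(cdr3nt != "", n),
             stringsAsFactors = FALSE)
}

# drop classing/metadata attributes for value-only comparisons
as_plain <- function(df) {
  df <- as.data.frame(df)
  attributes(df) <- attributes(df)[c("names", "row.names")]
  class(df) <- "data.frame"
  df
}

make_meta <- function(barcode, cluster, donor = "D01") {
  data.frame(barcode = barcode, donor_id = rep_len(donor, length(barcode)),
             cluster_id = rep_len(cluster, length(barcode)),
             stringsAsFactors = FALSE)
}

# independent all-pairs matching oracle: explicit loop over every
# (repertoire, cell) pair with elementwise key comparison
oracle_match <- function(subset_reps, cells, chain = "TRB",
                         match_key = "cdr3nt") {
  rows <- list()
  for (rep in subset_reps) {
    donor <- attr(rep, "donor_id")
    subset <- attr(rep, "subset_label")
    rep_rank <- if ("rank" %in% names(rep)) rep$rank else seq_len(nrow(rep))
    for (ci in seq_len(nrow(cells))) {
      if (cells$chain[ci] != chain || cells$donor_id[ci] != donor) next
      same <- rep$cdr3nt == cells$cdr3nt[ci]
      if (match_key == "cdr3nt_vj") {
        same <- same & rep$v_gene == cells$v_gene[ci] &
          rep$j_gene == cells$j_gene[ci]
      }
      hit <- which(same)
      if (length(hit)) {
        hit <- hit[1L]
        rows[[length(rows) + 1L]] <- data.frame(
          donor_id = donor, barcode = cells$barcode[ci],
          subset_label = subset, cdr3nt = cells$cdr3nt[ci],
          bulk_frequency = rep$frequency[hit], bulk_rank = rep_rank[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(donor_id = character(), barcode = character(),
               subset_label = character(), cdr3nt = character(),
               bulk_frequency = numeric(), bulk_rank = integer(),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$donor_id, out$subset_label, out$barcode, out$cdr3nt), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# random matching instance: a shared sequence pool guarantees hits
random_match_instance <- function(seed) {
  set.seed(seed)
  n_subsets <- sample(2:8, 1L)
  donors <- c("D01", "D04")
  pool <- random_nt(300L)
  vs <- sprintf("TRBV%d", 1:8)
  js <- sprintf("TRBJ%d", 1:4)
  reps <- list()
  for (d in donors) {
    for (s in seq_len(n_subsets)) {
      k <- sample(50:300, 1L)
      reps[[paste(d, s)]] <- bulk_repertoire(
        data.frame(cdr3nt = sample(pool, k),
                   v_gene = sample(vs, k, TRUE), j_gene = sample(js, k, TRUE),
                   count = sample(1:100, k, TRUE), stringsAsFactors = FALSE),
        donor_id = d, subset_label = paste0("S", s))
    }
  }
  n_cells <- sample(100:400, 1L)
  cells <- make_contigs(barcode = sprintf("BC%04d", seq_len(n_cells)),
                        cdr3nt = sample(pool, n_cells, replace = TRUE),
                        v = sample(vs, n_cells, TRUE),
                        j = sample(js, n_cells, TRUE),
                        donor = sample(donors, n_cells, TRUE))
  cells <- resolve_cell_chains(cells)
  list(reps = reps, cells = cells)
}
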