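# Synthetic clonal repertoire generator: donor-structured ground truth with
# power-law clone sizes, subset-specific cluster programs, sorting impurity,
# single-cell capture and noisy ADT counts. Emits exactly the table dialects
# the io module reads, so every pipeline stage is testable without external
# data.

# the 61 coding (non-stop) codons
.coding_codons <- local({
  nts <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(as.vector(outer(nts, nts, paste0)), nts, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

.translate_nt <- function(seqs) {
  vapply(seqs, function(s) {
    paste(seqinr::translate(seqinr::s2c(s)), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# n unique random in-frame CDR3s: 12-18 codons (36-54 nt, multiple of 3),
# built from coding codons only, so the translation never contains a stop.
.gen_cdr3 <- function(n, existing = character()) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 50L) stop("cannot generate enough unique CDR3 sequences")
    need <- n - length(out)
    lens <- sample(12:18, need, replace = TRUE)
    fresh <- vapply(lens, function(L) {
      paste(sample(.coding_codons, L, replace = TRUE), collapse = "")
    }, character(1L))
    fresh <- setdiff(unique(fresh), c(existing, out))
    out <- c(out, fresh)
  }
  out[seq_len(n)]
}

#' Default per-subset ADT panel means
#'
#' Negative-binomial mean ADT counts per (subset, marker), encoding the
#' classic sorting phenotypes: Treg CD25+CD127low; Tfh CXCR5+; Th22
#' CCR10+CCR6+CCR4+; Th1 CXCR3+; Th1-17 CCR6+CXCR3+; Th17 CCR6+CCR4+;
#' Th2 CCR4+; Th2a CCR4+CRTh2+. Positive markers get `pos_mean`, negative
#' `neg_mean`; CD127 sits at `cd127_base` on every subset except Treg.
#'
#' @param pos_mean,neg_mean,cd127_base mean counts.
#' @return Matrix subsets x markers of NB means.
#' @export
default_adt_panel <- function(pos_mean = 60, neg_mean = 5, cd127_base = 40) {
  subsets <- th_subset_labels()
  panel <- matrix(neg_mean, nrow = length(subsets),
                  ncol = length(.gating_markers),
                  dimnames = list(subsets, .gating_markers))
  panel[, "CD127"] <- cd127_base
  pos <- list(Treg = "CD25", Tfh = "CXCR5",
              Th22 = c("CCR10", "CCR6", "CCR4"),
              Th1 = "CXCR3", `Th1-17` = c("CCR6", "CXCR3"),
              Th17 = c("CCR6", "CCR4"), Th2 = "CCR4",
              Th2a = c("CCR4", "CRTh2"))
  for (s in names(pos)) panel[s, pos[[s]]] <- pos_mean
  panel["Treg", "CD127"] <- neg_mean
  panel
}

#' Synthetic study configuration
#'
#' Defines the ground-truth study the generator emulates: donors carrying
#' clonal repertoires per sorted subset (clone sizes following a discrete
#' power law), subset programs concentrated on distinct transcriptome
#' clusters, sorting impurity routing clones of one subset into another
#' subset's tube, single-cell capture with optional decoy contigs, and a
#' noisy ADT panel.
#'
#' @param n_donors number of donors.
#' @param cells_per_donor single cells drawn per donor.
#' @param clones_per_subset clones per donor per subset.
#' @param subsets,clusters label vectors.
#' @param subset_clusters named map subset -> its program's dominant cluster
#'   (default: the identically named cluster).
#' @param concentration probability mass the program places on the dominant
#'   cluster (rest spread uniformly); a full `programs` matrix overrides.
#' @param programs optional subsets x clusters probability matrix.
#' @param powerlaw_exponent,max_clone_size clone-size law: P(size = k)
#'   proportional to k^-exponent, k = 1..max_clone_size.
#' @param bulk_depth reads per sorted tube (multinomial total).
#' @param capture_rate probability a cell yields a TRB (and, independently,
#'   a TRA) contig.
#' @param decoy_fraction fraction of captured cells receiving a second,
#'   lower-UMI TRB contig (exercises chain resolution).
#' @param impurity subsets x subsets routing matrix: probability a clone of
#'   subset (row) is also sorted into the tube of subset (column); default
#'   identity (pure sorting).
#' @param cross_donor_collision_rate fraction of each later donor's clones
#'   sharing a CDR3 with donor 1 (tests donor scoping; default 0).
#' @param adt_panel subsets x markers NB mean matrix
#'   ([default_adt_panel()]).
#' @param adt_dispersion NB size parameter (`Inf` = Poisson).
#' @param batch_effects named per-batch multipliers on ADT means (batches are
#'   donors); default none.
#' @param seed base RNG seed, recorded in all outputs.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_donors = 3L,
                             cells_per_donor = 2000L,
                             clones_per_subset = 800L,
                             subsets = th_subset_labels(),
                             clusters = th_cluster_labels(),
                             subset_clusters = NULL,
                             concentration = 0.85,
                             programs = NULL,
                             powerlaw_exponent = 2.5,
                             max_clone_size = 5000L,
                             bulk_depth = 30000L,
                             capture_rate = 0.95,
                             decoy_fraction = 0.1,
                             impurity = NULL,
                             cross_donor_collision_rate = 0,
                             adt_panel = default_adt_panel(),
                             adt_dispersion = 2,
                             batch_effects = NULL,
                             seed = 1L) {
  stopifnot(n_donors >= 1L, cells_per_donor >= 1L, clones_per_subset >= 1L,
            bulk_depth >= 1L,
            capture_rate >= 0, capture_rate <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1,
            concentration > 0, concentration <= 1,
            cross_donor_collision_rate >= 0, cross_donor_collision_rate <= 1)
  if (is.null(subset_clusters)) {
    stopifnot(all(subsets %in% clusters))
    subset_clusters <- stats::setNames(subsets, subsets)
  }
  if (is.null(programs)) {
    k <- length(clusters)
    programs <- matrix((1 - concentration) / (k - 1), nrow = length(subsets),
                       ncol = k, dimnames = list(subsets, clusters))
    for (s in subsets) programs[s, subset_clusters[[s]]] <- concentration
  }
  stopifnot(all(abs(rowSums(programs) - 1) < 1e-9), all(programs >= 0))
  if (is.null(impurity)) {
    impurity <- diag(length(subsets))
    dimnames(impurity) <- list(subsets, subsets)
  }
  stopifnot(all(impurity >= 0), all(impurity <= 1),
            identical(rownames(impurity), subsets))
  structure(list(n_donors = as.integer(n_donors),
                 donors = sprintf("D%02d", seq_len(n_donors)),
                 cells_per_donor = as.integer(cells_per_donor),
                 clones_per_subset = as.integer(clones_per_subset),
                 subsets = subsets, clusters = clusters,
                 programs = programs,
                 powerlaw_exponent = powerlaw_exponent,
                 max_clone_size = as.integer(max_clone_size),
                 bulk_depth = as.integer(bulk_depth),
                 capture_rate = capture_rate,
                 decoy_fraction = decoy_fraction,
                 impurity = impurity,
                 cross_donor_collision_rate = cross_donor_collision_rate,
                 adt_panel = adt_panel,
                 adt_dispersion = adt_dispersion,
                 batch_effects = batch_effects,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate the ground truth of a synthetic study
#'
#' Creates the clone registry: per donor and subset, `clones_per_subset`
#' clones with unique in-frame CDR3 nucleotide sequences (36-54 nt, multiple
#' of 3, no stop codon in translation) for both TRB and TRA, random V/J
#' calls, and power-law clone sizes. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_truth`: list with `clones` (registry data.frame),
#'   `programs` and `config`.
#' @export
make_truth <- function(config) {
  .with_seed(config$seed, {
    n_sub <- length(config$subsets)
    per_donor <- n_sub * config$clones_per_subset
    size_support <- seq_len(config$max_clone_size)
    size_prob <- size_support^(-config$powerlaw_exponent)
    clones <- do.call(rbind, lapply(config$donors, function(d) {
      trb <- .gen_cdr3(per_donor)
      tra <- .gen_cdr3(per_donor)
      data.frame(donor_id = d,
                 clone_id = sprintf("%s_c%05d", d, seq_len(per_donor)),
                 subset_label = rep(config$subsets,
                                    each = config$clones_per_subset),
                 cdr3nt = trb,
                 cdr3aa = .translate_nt(trb),
                 v_gene = sample(sprintf("TRBV%d", 1:30), per_donor, TRUE),
                 j_gene = sample(sprintf("TRBJ%d-%d", rep(1:2, each = 6),
                                         rep(1:6, 2)), per_donor, TRUE),
                 cdr3nt_tra = tra,
                 cdr3aa_tra = .translate_nt(tra),
                 size = sample(size_support, per_donor, replace = TRUE,
                               prob = size_prob),
                 stringsAsFactors = FALSE)
    }))
    rate <- config$cross_donor_collision_rate
    if (rate > 0 && config$n_donors > 1L) {
      donor1 <- clones$cdr3nt[clones$donor_id == config$donors[1L]]
      for (d in config$donors[-1L]) {
        rows <- which(clones$donor_id == d)
        n_coll <- floor(rate * length(rows))
        if (n_coll >= 1L) {
          take <- sample(rows, n_coll)
          clones$cdr3nt[take] <- sample(donor1, n_coll)
        }
      }
    }
    structure(list(clones = clones, programs = config$programs,
                   config = config),
              class = "synthetic_truth")
  })
}

#' Draw the bulk repertoires of the sorted tubes
#'
#' Each donor x subset tube receives reads multinomially, at `bulk_depth`,
#' from the clone sizes of the subsets routed to it by the impurity matrix
#' (each clone of subset s lands in tube t with probability `impurity[s, t]`,
#' carrying its full clone size — a sorting impurity moves the clone's cells,
#' not a fraction of them). Clonotypes drawing zero reads are absent from the
#' table, as in a real sequencing run.
#'
#' @param truth a [make_truth()] result.
#' @param chain which chain's CDR3 keys to emit.
#' @param seed RNG seed (default derives from the config seed).
#' @return list: `repertoires` (named `"donor|subset"` list of
#'   [bulk_repertoire()]s) and `routing` (data.frame recording which clones
#'   entered which tube, with their source subset — the contamination ground
#'   truth).
#' @export
sample_bulk_repertoires <- function(truth, chain = c("TRB", "TRA"),
                                    seed = truth$config$seed + 1L) {
  chain <- match.arg(chain)
  config <- truth$config
  nt_col <- if (chain == "TRB") "cdr3nt" else "cdr3nt_tra"
  aa_col <- if (chain == "TRB") "cdr3aa" else "cdr3aa_tra"
  .with_seed(seed, {
    reps <- list()
    routing <- list()
    for (d in config$donors) {
      dc <- truth$clones[truth$clones$donor_id == d, , drop = FALSE]
      for (tube in config$subsets) {
        p_route <- config$impurity[dc$subset_label, tube]
        routed <- stats::runif(nrow(dc)) < p_route
        rc <- dc[routed, , drop = FALSE]
        if (nrow(rc) == 0L) next
        draws <- stats::rmultinom(1L, config$bulk_depth, prob = rc$size)[, 1L]
        keep <- draws > 0L
        rep <- bulk_repertoire(
          data.frame(cdr3nt = rc[[nt_col]][keep],
                     cdr3aa = rc[[aa_col]][keep],
                     v_gene = rc$v_gene[keep],
                     j_gene = rc$j_gene[keep],
                     count = draws[keep],
                     stringsAsFactors = FALSE),
          donor_id = d, subset_label = tube, chain = chain)
        reps[[paste(d, tube, sep = "|")]] <- rep
        routing[[paste(d, tube, sep = "|")]] <-
          data.frame(donor_id = d, tube = tube,
                     clone_id = rc$clone_id[keep],
                     source_subset = rc$subset_label[keep],
                     cdr3nt = rc[[nt_col]][keep],
                     count = draws[keep],
                     stringsAsFactors = FALSE)
      }
    }
    list(repertoires = reps, routing = do.call(rbind, c(routing,
                                                        make.row.names = FALSE)))
  })
}

#' Draw single cells from the ground truth
#'
#' Each cell samples a clone (size-weighted across the donor's full
#' registry), a cluster from the clone's subset program, and — with
#' probability `capture_rate` per chain — emits a 10x-dialect contig row.
#' A `decoy_fraction` of the captured cells receives a second TRB contig at
#' UMI 1 (below the true contig's UMI) with a CDR3 outside the registry, to
#' exercise most-abundant-chain resolution.
#'
#' @param truth a [make_truth()] result.
#' @param seed RNG seed.
#' @return list: `contigs` (named per-donor list of raw 10x-dialect
#'   data.frames), `contig_records` (the same tables normalized through
#'   [read_sc_contigs()]), `meta` (cell metadata for all cells) and
#'   `cell_truth` (per-cell ground truth: clone, true subset, cluster,
#'   capture/decoy flags).
#' @export
sample_single_cells <- function(truth, seed = truth$config$seed + 2L) {
  config <- truth$config
  .with_seed(seed, {
    per_donor <- lapply(config$donors, function(d) {
      dc <- truth$clones[truth$clones$donor_id == d, , drop = FALSE]
      n <- config$cells_per_donor
      pick <- sample(nrow(dc), n, replace = TRUE, prob = dc$size)
      cells <- dc[pick, c("clone_id", "subset_label", "cdr3nt", "cdr3aa",
                          "v_gene", "j_gene", "cdr3nt_tra", "cdr3aa_tra"),
                  drop = FALSE]
      # cluster drawn from the clone's subset program
      cells$cluster_id <- NA_character_
      for (s in unique(cells$subset_label)) {
        rows <- which(cells$subset_label == s)
        cells$cluster_id[rows] <- sample(config$clusters, length(rows),
                                         replace = TRUE,
                                         prob = config$programs[s, ])
      }
      # unique 10x-style barcodes
      repeat {
        bc <- apply(matrix(sample(c("A", "C", "G", "T"), 16L * n,
                                  replace = TRUE), nrow = n), 1L,
                    paste, collapse = "")
        bc <- paste0(bc, "-1")
        if (!anyDuplicated(bc)) break
      }
      cells$barcode <- bc
      cells$captured_trb <- stats::runif(n) < config$capture_rate
      cells$captured_tra <- stats::runif(n) < config$capture_rate
      cells$has_decoy <- cells$captured_trb &
        stats::runif(n) < config$decoy_fraction
      umi_trb <- 2L + stats::rpois(n, 3)
      umi_tra <- 2L + stats::rpois(n, 3)

      contig_row <- function(idx, chain, nt, aa, umi) {
        data.frame(barcode = cells$barcode[idx],
                   is_cell = "True", high_confidence = "True",
                   chain = chain,
                   v_gene = if (chain == "TRB") cells$v_gene[idx] else "TRAV1",
                   d_gene = "None",
                   j_gene = if (chain == "TRB") cells$j_gene[idx] else "TRAJ1",
                   c_gene = paste0(chain, "C"),
                   full_length = "True", productive = "True",
                   cdr3 = aa, cdr3_nt = nt,
                   reads = umi * 10L, umis = umi,
                   stringsAsFactors = FALSE)
      }
      trb_idx <- which(cells$captured_trb)
      tra_idx <- which(cells$captured_tra)
      parts <- list(
        contig_row(trb_idx, "TRB", cells$cdr3nt[trb_idx],
                   cells$cdr3aa[trb_idx], umi_trb[trb_idx]),
        contig_row(tra_idx, "TRA", cells$cdr3nt_tra[tra_idx],
                   cells$cdr3aa_tra[tra_idx], umi_tra[tra_idx]))
      decoy_idx <- which(cells$has_decoy)
      if (length(decoy_idx)) {
        decoy_nt <- .gen_cdr3(length(decoy_idx), existing = dc$cdr3nt)
        parts <- c(parts, list(contig_row(decoy_idx, "TRB", decoy_nt,
                                          .translate_nt(decoy_nt),
                                          rep(1L, length(decoy_idx)))))
      }
      contigs <- do.call(rbind, parts)
      contigs <- contigs[order(contigs$barcode, contigs$chain,
                               -contigs$umis), , drop = FALSE]
      rownames(contigs) <- NULL
      list(donor = d, contigs = contigs,
           meta = data.frame(barcode = cells$barcode, donor_id = d,
                             cluster_id = cells$cluster_id,
                             stringsAsFactors = FALSE),
           cell_truth = data.frame(donor_id = d, barcode = cells$barcode,
                                   clone_id = cells$clone_id,
                                   subset_label = cells$subset_label,
                                   cluster_id = cells$cluster_id,
                                   captured_trb = cells$captured_trb,
                                   captured_tra = cells$captured_tra,
                                   has_decoy = cells$has_decoy,
                                   stringsAsFactors = FALSE))
    })
    contigs <- stats::setNames(lapply(per_donor, `[[`, "contigs"),
                               config$donors)
    records <- do.call(rbind, c(lapply(config$donors, function(d) {
      read_sc_contigs(contigs[[d]], donor_id = d)
    }), make.row.names = FALSE))
    list(contigs = contigs,
         contig_records = records,
         meta = do.call(rbind, c(lapply(per_donor, `[[`, "meta"),
                                 make.row.names = FALSE)),
         cell_truth = do.call(rbind, c(lapply(per_donor, `[[`, "cell_truth"),
                                       make.row.names = FALSE)))
  })
}

#' Draw noisy ADT counts for simulated cells
#'
#' Marker counts follow a negative binomial with subset-dependent mean (the
#' config's ADT panel), NB size `adt_dispersion` (`Inf` switches to Poisson)
#' and optional per-batch multipliers; each donor is one staining batch.
#'
#' @param cell_truth the `cell_truth` table from [sample_single_cells()].
#' @param config the [synthetic_config()].
#' @param seed RNG seed.
#' @return An [adt_matrix()] with cells keyed by [cell_key()].
#' @export
sample_adt <- function(cell_truth, config, seed = config$seed + 3L) {
  .with_seed(seed, {
    panel <- config$adt_panel
    n <- nrow(cell_truth)
    batch <- cell_truth$donor_id
    mult <- rep(1, n)
    if (!is.null(config$batch_effects)) {
      m <- config$batch_effects[batch]
      mult <- ifelse(is.na(m), 1, m)
    }
    counts <- matrix(0, nrow = n, ncol = ncol(panel),
                     dimnames = list(cell_key(cell_truth$donor_id,
                                              cell_truth$barcode),
                                     colnames(panel)))
    mu <- panel[cell_truth$subset_label, , drop = FALSE] * mult
    for (k in seq_len(ncol(panel))) {
      counts[, k] <- if (is.infinite(config$adt_dispersion)) {
        stats::rpois(n, mu[, k])
      } else {
        stats::rnbinom(n, mu = mu[, k], size = config$adt_dispersion)
      }
    }
    adt_matrix(counts, batch = batch)
  })
}

#' Run the whole generator
#'
#' @param config a [synthetic_config()].
#' @return list: `truth`, `bulk` (repertoire list), `routing`, `contigs`,
#'   `contig_records`, `meta`, `cell_truth`, `adt`, `config`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  truth <- make_truth(config)
  bulk <- sample_bulk_repertoires(truth)
  sc <- sample_single_cells(truth)
  adt <- sample_adt(sc$cell_truth, config)
  list(truth = truth, bulk = bulk$repertoires, routing = bulk$routing,
       contigs = sc$contigs, contig_records = sc$contig_records,
       meta = sc$meta, cell_truth = sc$cell_truth, adt = adt, config = config)
}

#' Write a simulated study to disk in the external formats
#'
#' Produces the layout the CLI consumes: `bulk/<donor>_<subset>.tsv`
#' (VDJtools dialect), `contigs/<donor>.csv` (10x dialect), `meta.tsv`,
#' `adt_counts.tsv` + `adt_batches.tsv`, a `truth/` directory of ground-truth
#' tables, and `metadata.json` recording the seed and parameters.
#'
#' @param sim a [simulate_study()] result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  for (sub in c("", "bulk", "contigs", "truth")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE, recursive = TRUE)
  }
  for (k in names(sim$bulk)) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    write_bulk_repertoire(sim$bulk[[k]],
                          file.path(out_dir, "bulk",
                                    paste0(parts[1L], "_", parts[2L], ".tsv")))
  }
  for (d in names(sim$contigs)) {
    utils::write.csv(sim$contigs[[d]],
                     file.path(out_dir, "contigs", paste0(d, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  .write_tsv(sim$meta, file.path(out_dir, "meta.tsv"))
  adt_df <- data.frame(cell = rownames(sim$adt$counts), sim$adt$counts,
                       check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(adt_df, file.path(out_dir, "adt_counts.tsv"))
  .write_tsv(data.frame(cell = rownames(sim$adt$counts),
                        batch = sim$adt$batch, stringsAsFactors = FALSE),
             file.path(out_dir, "adt_batches.tsv"))
  .write_tsv(sim$truth$clones, file.path(out_dir, "truth", "clones.tsv"))
  .write_tsv(sim$cell_truth, file.path(out_dir, "truth", "cell_truth.tsv"))
  if (!is.null(sim$routing)) {
    .write_tsv(sim$routing, file.path(out_dir, "truth", "routing.tsv"))
  }
  .write_matrix_tsv(sim$config$programs, file.path(out_dir, "truth",
                                                   "programs.tsv"),
                    label = "subset")
  cfg <- sim$config
  scalar <- cfg[vapply(cfg, function(x) is.atomic(x) && length(x) == 1L,
                       logical(1L))]
  jsonlite::write_json(c(scalar, list(tool_version =
    as.character(utils::packageVersion("tcrtrack")))),
    file.path(out_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
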