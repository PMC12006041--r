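small_cfg <- function(...) {
  synthetic_config(n_donors = 2, cells_per_donor = 300,
                   clones_per_subset = 80, seed = 9, ...)
}

test_that("ground truth is deterministic, unique per donor and in-frame", {
  cfg <- small_cfg()
  t1 <- make_truth(cfg)
  t2 <- make_truth(cfg)
  expect_identical(t1$clones, t2$clones)
  for (d in cfg$donors) {
    dc <- t1$clones[t1$clones$donor_id == d, ]
    expect_equal(anyDuplicated(dc$cdr3nt), 0L)
  }
  expect_true(all(nchar(t1$clones$cdr3nt) %% 3 == 0))
  expect_true(all(nchar(t1$clones$cdr3nt) >= 36 &
                    nchar(t1$clones$cdr3nt) <= 54))
  expect_false(any(grepl("*", t1$clones$cdr3aa, fixed = TRUE)))
})

test_that("cross-donor CDR3 collisions are injectable", {
  pure <- make_truth(small_cfg())
  d1 <- pure$clones$cdr3nt[pure$clones$donor_id == "D01"]
  d2 <- pure$clones$cdr3nt[pure$clones$donor_id == "D02"]
  expect_equal(length(intersect(d1, d2)), 0L)
  shared <- make_truth(small_cfg(cross_donor_collision_rate = 0.1))
  s1 <- shared$clones$cdr3nt[shared$clones$donor_id == "D01"]
  s2 <- shared$clones$cdr3nt[shared$clones$donor_id == "D02"]
  expect_gte(length(intersect(s1, s2)), 0.05 * length(s2))
})

test_that("a degenerate program puts every cell of the subset in its cluster", {
  cfg <- small_cfg(concentration = 1)
  sim <- simulate_study(cfg)
  th1 <- sim$cell_truth[sim$cell_truth$subset_label == "Th1", ]
  expect_true(all(th1$cluster_id == "Th1"))
})

test_that("bulk tubes draw the configured depth and respect the impurity matrix", {
  cfg <- small_cfg(bulk_depth = 10000)
  truth <- make_truth(cfg)
  bulk <- sample_bulk_repertoires(truth)
  rep <- bulk$repertoires[["D01|Th17"]]
  expect_equal(sum(rep$count), 10000L)
  expect_equal(sum(rep$frequency), 1)
  # identity impurity: every tube holds only its own subset's clones
  own <- truth$clones$cdr3nt[truth$clones$donor_id == "D01" &
                               truth$clones$subset_label == "Th17"]
  expect_true(all(rep$cdr3nt %in% own))

  subsets <- th_subset_labels()
  imp <- diag(length(subsets)); dimnames(imp) <- list(subsets, subsets)
  imp["Th22", "Th17"] <- 0.5
  mixed <- sample_bulk_repertoires(make_truth(small_cfg(impurity = imp)))
  contam <- mixed$routing[mixed$routing$tube == "Th17" &
                            mixed$routing$source_subset == "Th22", ]
  expect_gt(nrow(contam), 0)
  th22_tube <- mixed$repertoires[["D01|Th22"]]
  in_both <- intersect(mixed$repertoires[["D01|Th17"]]$cdr3nt, th22_tube$cdr3nt)
  expect_gt(length(in_both), 0)
})

test_that("full capture yields a resolved TRB for every cell, and decoys lose to the true contig", {
  cfg <- small_cfg(capture_rate = 1, decoy_fraction = 0.25)
  sim <- simulate_study(cfg)
  cells <- resolve_cell_chains(filter_contigs(sim$contig_records))
  trb <- cells[cells$chain == "TRB", ]
  expect_equal(nrow(trb), nrow(sim$cell_truth))
  # every decoy cell carries two TRB contigs and resolution keeps the truth
  truth_nt <- sim$truth$clones$cdr3nt[match(sim$cell_truth$clone_id,
                                            sim$truth$clones$clone_id)]
  expect_equal(trb$cdr3nt[match(cell_key(sim$cell_truth$donor_id,
                                         sim$cell_truth$barcode),
                                cell_key(trb$donor_id, trb$barcode))],
               truth_nt)
  decoys <- sim$cell_truth[sim$cell_truth$has_decoy, ]
  expect_gt(nrow(decoys), 0)
  rec <- sim$contig_records
  n_trb <- table(cell_key(rec$donor_id[rec$chain == "TRB"],
                          rec$barcode[rec$chain == "TRB"]))
  expect_true(all(n_trb[cell_key(decoys$donor_id, decoys$barcode)] == 2L))
})

test_that("cluster draws follow the subset program within sampling error", {
  cfg <- synthetic_config(n_donors = 1, cells_per_donor = 2000,
                          clones_per_subset = 100, concentration = 0.85,
                          seed = 17)
  sim <- simulate_study(cfg)
  th17 <- sim$cell_truth[sim$cell_truth$subset_label == "Th17", ]
  frac <- mean(th17$cluster_id == "Th17")
  se <- sqrt(0.85 * 0.15 / nrow(th17))
  expect_lt(abs(frac - 0.85), 3 * se)
})

test_that("ADT counts track their configured means, batches and limits", {
  # Poisson limit: sample mean within 3 SE of the panel mean
  cfg <- small_cfg(adt_dispersion = Inf)
  sim <- simulate_study(cfg)
  treg <- sim$adt$counts[sim$cell_truth$subset_label == "Treg", "CD25"]
  mu <- cfg$adt_panel["Treg", "CD25"]
  expect_lt(abs(mean(treg) - mu), 3 * sqrt(mu / length(treg)))

  # batch multiplier doubles every marker's mean in the second batch
  cfg2 <- small_cfg(batch_effects = c(D01 = 1, D02 = 2))
  sim2 <- simulate_study(cfg2)
  m1 <- colMeans(sim2$adt$counts[sim2$adt$batch == "D01", ])
  m2 <- colMeans(sim2$adt$counts[sim2$adt$batch == "D02", ])
  expect_equal(unname(m2 / m1), rep(2, length(m1)), tolerance = 0.25)

  # zero-mean marker stays all-zero
  panel <- default_adt_panel()
  panel[, "CRTh2"] <- 0
  sim3 <- simulate_study(small_cfg(adt_panel = panel))
  expect_true(all(sim3$adt$counts[, "CRTh2"] == 0))
})

test_that("simulated outputs round-trip through the io readers", {
  sim <- simulate_study(small_cfg())
  out <- withr::local_tempdir()
  write_simulation(sim, out)
  rep_back <- read_bulk_repertoire(file.path(out, "bulk", "D01_Th17.tsv"),
                                   "D01", "Th17")
  expect_equal(rep_back$cdr3nt, sim$bulk[["D01|Th17"]]$cdr3nt)
  expect_equal(rep_back$count, sim$bulk[["D01|Th17"]]$count)
  contigs_back <- read_sc_contigs(file.path(out, "contigs", "D01.csv"), "D01")
  expect_equal(nrow(contigs_back),
               sum(sim$contig_records$donor_id == "D01"))
  meta_back <- read_cluster_assignments(file.path(out, "meta.tsv"))
  expect_equal(nrow(meta_back), nrow(sim$meta))
  adt_back <- read_adt_matrix(file.path(out, "adt_counts.tsv"))
  expect_equal(unname(adt_back$counts), unname(sim$adt$counts))
  expect_true(file.exists(file.path(out, "metadata.json")))
})
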