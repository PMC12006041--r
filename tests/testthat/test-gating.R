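adt_fixture <- function(counts, markers, batch = NULL) {
  m <- matrix(counts, ncol = length(markers), byrow = TRUE,
              dimnames = list(sprintf("c%02d", seq_len(length(counts) %/%
                                                         length(markers))),
                              markers))
  adt_matrix(m, batch = batch)
}

test_that("CLR normalization reproduces the worked example", {
  adt <- adt_fixture(c(1, 4, 0), c("m1", "m2", "m3"))
  norm <- clr_normalize(adt, margin = "per_cell")
  g <- 4^(1 / 3)
  expect_equal(unname(norm$values[1, ]), c(log1p(1 / g), log1p(4 / g), 0),
               tolerance = 1e-12)
})

test_that("CLR symmetry and zero-vector cases", {
  # all entries equal c > 0: geometric mean is c, every value is ln 2
  adt <- adt_fixture(rep(7, 4), sprintf("m%d", 1:4))
  expect_equal(unname(clr_normalize(adt)$values[1, ]), rep(log(2), 4))
  # an all-zero panel stays at zero
  zero <- adt_fixture(c(0, 0, 0, 5, 2, 1), sprintf("m%d", 1:3))
  expect_warning(norm <- clr_normalize(zero), "all-zero")
  expect_equal(unname(norm$values[1, ]), c(0, 0, 0))
})

test_that("per-marker CLR respects batch boundaries", {
  adt <- adt_fixture(c(1, 10, 4, 10, 1, 20, 4, 20), c("m1", "m2"),
                     batch = rep(c("b1", "b2"), each = 2))
  pooled <- clr_normalize(adt, margin = "per_marker", batchwise = FALSE)
  split <- clr_normalize(adt, margin = "per_marker", batchwise = TRUE)
  # within-batch m1 columns are identical up to batch composition
  clr_vec <- function(x) log1p(x / exp(sum(log(x[x > 0])) / length(x)))
  expect_equal(unname(split$values[1:2, "m1"]), clr_vec(c(1, 4)))
  expect_equal(unname(pooled$values[, "m1"]), clr_vec(c(1, 4, 1, 4)))
  expect_false(identical(pooled$values, split$values))
})

test_that("sequential gating consumes cells in hierarchy order", {
  markers <- c("CD25", "CD127", "CXCR5", "CXCR3", "CCR6", "CCR4", "CRTh2",
               "CCR10")
  # cell 1: Treg phenotype (also CCR10 high, but Treg node consumes first);
  # cell 2: Th22; cell 3: below every positive threshold
  values <- rbind(c(2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 2),
                  c(0.1, 2, 0.1, 0.1, 2, 2, 0.1, 2),
                  c(0.1, 2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  colnames(values) <- markers
  rownames(values) <- c("c1", "c2", "c3")
  norm <- structure(list(values = values, cells = rownames(values),
                         markers = markers, batch = rep("b1", 3),
                         method = "clr", margin = "per_cell",
                         batchwise = FALSE), class = "normalized_adt")
  thr <- setNames(rep(1, length(markers)), markers)
  labels <- apply_gate_sequence(norm, default_gate_spec(thr))
  expect_equal(unname(labels), c("Treg", "Th22", "ungated"))

  # each cell gets at most one label
  expect_equal(length(labels), 3L)

  # a marker in neither panel nor fallback is a configuration error
  norm2 <- norm
  norm2$values <- norm2$values[, markers != "CCR10"]
  expect_error(apply_gate_sequence(norm2, default_gate_spec(thr)),
               "configuration error")
  # ... but an RNA fallback column rescues it
  fb <- matrix(values[, "CCR10"], ncol = 1,
               dimnames = list(rownames(values), "CCR10"))
  labels_fb <- apply_gate_sequence(norm2, default_gate_spec(thr),
                                   rna_fallback = fb)
  expect_equal(unname(labels_fb), unname(labels))
})

test_that("raising a positive threshold never grows the gated subset", {
  set.seed(21)
  cfg <- synthetic_config(n_donors = 1, cells_per_donor = 400,
                          clones_per_subset = 100, seed = 3)
  sim <- simulate_study(cfg)
  norm <- clr_normalize(sim$adt)
  thr <- setNames(rep(0.7, 8), colnames(norm$values))
  n_treg <- vapply(c(0.5, 0.8, 1.1, 1.4), function(t) {
    thr["CD25"] <- t
    sum(apply_gate_sequence(norm, default_gate_spec(thr)) == "Treg")
  }, numeric(1))
  expect_true(all(diff(n_treg) <= 0))
})

test_that("the exhaustive optimizer matches an independent grid enumeration", {
  set.seed(31)
  cfg <- synthetic_config(n_donors = 1, cells_per_donor = 500,
                          clones_per_subset = 100, seed = 13)
  sim <- simulate_study(cfg)
  norm <- clr_normalize(sim$adt)
  clusters <- sim$meta$cluster_id
  qs <- function(m, p) unname(quantile(norm$values[, m], p))
  grids <- list(CD25 = qs("CD25", c(0.5, 0.7, 0.9)),
                CCR6 = qs("CCR6", c(0.4, 0.6, 0.8)),
                CCR4 = qs("CCR4", c(0.4, 0.6, 0.8)),
                CD127 = qs("CD127", 0.4), CXCR5 = qs("CXCR5", 0.7),
                CXCR3 = qs("CXCR3", 0.6), CRTh2 = qs("CRTh2", 0.7),
                CCR10 = qs("CCR10", 0.7))
  fit <- optimize_gate_thresholds(norm, grids, clusters)

  # oracle: enumerate every combination independently of the optimizer
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  objs <- vapply(seq_len(nrow(combos)), function(k) {
    labs <- apply_gate_sequence(norm,
                                default_gate_spec(as.list(combos[k, ])))
    s <- shannon_by_subset(labs, clusters)
    if (any(s$defined)) mean(s$shannon[s$defined]) else NA_real_
  }, numeric(1))
  expect_equal(fit$objective, min(objs, na.rm = TRUE))
  expect_equal(nrow(fit$report), 27L)

  # determinism and the single-candidate degenerate case
  fit2 <- optimize_gate_thresholds(norm, grids, clusters)
  expect_identical(fit$thresholds, fit2$thresholds)
  single <- lapply(grids, `[[`, 1L)
  fit1 <- optimize_gate_thresholds(norm, lapply(single, identity), clusters)
  expect_equal(fit1$thresholds[order(names(fit1$thresholds))],
               single[order(names(single))], tolerance = 1e-12)
})

test_that("gate specs round-trip through the YAML config format", {
  thr <- setNames(seq(0.1, 0.8, 0.1),
                  c("CD25", "CD127", "CXCR5", "CXCR3", "CCR6", "CCR4",
                    "CRTh2", "CCR10"))
  spec <- default_gate_spec(thr)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_gate_spec(spec, tf)
  back <- read_gate_spec(tf)
  expect_equal(length(back), length(spec))
  expect_equal(back[[1]]$label, spec[[1]]$label)
  expect_equal(back[[5]]$markers, spec[[5]]$markers)
})
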