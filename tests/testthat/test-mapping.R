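test_that("normalized Shannon index matches closed forms", {
  # single occupied cluster: maximal focus
  expect_equal(shannon_accuracy(c(1, 0, 0), n_cells = 20), 0)
  # uniform over k occupied clusters: maximal evenness
  for (k in c(2, 4, 8)) {
    expect_equal(shannon_accuracy(rep(1 / k, k), n_cells = 12), 1)
  }
  # frozen from direct evaluation of -sum(p log p)/log 3
  expect_equal(shannon_accuracy(c(0.5, 0.25, 0.25), n_cells = 12),
               0.946395, tolerance = 1e-6)
})

test_that("the min-cells rule excludes small subsets", {
  p <- c(0.5, 0.25, 0.25)
  expect_true(is.na(shannon_accuracy(p, n_cells = 7)))
  expect_false(is.na(shannon_accuracy(p, n_cells = 8)))
  expect_true(is.na(shannon_accuracy(p, n_cells = 3, min_cells = 4)))
})

test_that("Shannon input validation", {
  expect_error(shannon_accuracy(c(0.5, 0.2), n_cells = 10), "sum to")
  expect_error(shannon_accuracy(c(-0.1, 1.1), n_cells = 10), "negative")
  expect_true(is.na(shannon_accuracy(c(0, 0, 0))))
})

test_that("Shannon index is invariant to label permutation and empty clusters,
           and decreases under concentration", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    p <- as.vector(rmultinom(1, 200, runif(k))) / 200
    s <- shannon_accuracy(p, n_cells = 200)
    expect_equal(shannon_accuracy(sample(p), n_cells = 200), s)
    expect_equal(shannon_accuracy(c(p, 0, 0, 0), n_cells = 200), s)
    # move mass from a minor occupied cluster into the major one
    occ <- which(p > 0)
    if (length(occ) < 3) next
    minor <- occ[which.min(p[occ])]
    major <- occ[which.max(p[occ])]
    if (minor == major) next
    q <- p
    shift <- q[minor] / 2
    q[minor] <- q[minor] - shift
    q[major] <- q[major] + shift
    expect_lt(shannon_accuracy(q, n_cells = 200), s)
  }
})

test_that("mapping matrices follow the dot-plot arithmetic", {
  bcs <- sprintf("B%03d", 1:108)
  meta <- make_meta(bcs, rep(c("A", "B"), c(100, 8)))
  # subset X: 6 cells in cluster A, 2 in cluster B
  mt <- data.frame(donor_id = "D01",
                   barcode = c(bcs[1:6], bcs[101:102]),
                   subset_label = "X",
                   cdr3nt = "TGTGCC", bulk_frequency = 0.1, bulk_rank = 1L)
  res <- suppressWarnings(compute_mapping_matrices(mt, meta, min_cells = 2L))
  expect_equal(unname(res$size["X", c("A", "B")]), c(0.75, 0.25))
  # universe is the annotated cells only: 6 of the 6 A-cells are matched
  expect_equal(unname(res$counts["X", "A"]), 6L)
  expect_equal(unname(res$intensity["X", "A"]), 1)

  # intensity against the full-cohort cluster size needs no subsampling of meta:
  # integer consistency n_ij = intensity_ij * cluster_size_i = size_ij * total_j
  n_back1 <- res$intensity["X", ] * res$cluster_sizes
  n_back2 <- res$size["X", ] * sum(res$counts["X", ])
  expect_equal(unname(n_back1), unname(res$counts["X", ]))
  expect_equal(unname(n_back2), unname(res$counts["X", ]))
})

test_that("matched cells without a cluster label are an integrity error", {
  meta <- make_meta("B1", "A")
  mt <- data.frame(donor_id = "D01", barcode = "B9", subset_label = "X",
                   cdr3nt = "TGT", bulk_frequency = 1, bulk_rank = 1L)
  expect_error(compute_mapping_matrices(mt, meta), "B9")
})

test_that("an empty match table yields zero matrices and undefined indices", {
  meta <- make_meta(c("B1", "B2"), c("A", "B"))
  mt <- data.frame(donor_id = character(), barcode = character(),
                   subset_label = character(), cdr3nt = character(),
                   bulk_frequency = numeric(), bulk_rank = integer())
  res <- suppressWarnings(compute_mapping_matrices(mt, meta, subsets = c("Th1", "Th17")))
  expect_true(all(res$counts == 0))
  expect_true(all(!res$shannon$defined))
})

test_that("subsampling is seeded, capped and reproducible", {
  keys <- sprintf("D01|%05d", 1:30000)
  s1 <- subsample_matched_cells(keys, n = 20000, seed = 5)
  s2 <- subsample_matched_cells(keys[sample(30000)], n = 20000, seed = 5)
  expect_equal(length(s1), 20000L)
  expect_identical(s1, s2)
  s3 <- subsample_matched_cells(keys, n = 20000, seed = 6)
  expect_equal(length(s3), 20000L)
  expect_false(identical(s1, s3))
  expect_warning(all5k <- subsample_matched_cells(keys[1:5000], n = 20000),
                 "using all")
  expect_equal(length(all5k), 5000L)
  expect_error(subsample_matched_cells(keys, n = 100), "seed")
})

test_that("accuracy comparison gives exact rank-sum p-values on small samples", {
  # independent enumeration oracle over all rank assignments
  oracle_p <- function(a, b) {
    r <- rank(c(a, b)); n <- length(a)
    w <- apply(combn(length(r), n), 2, function(ix) sum(r[ix]))
    mu <- n * (length(r) + 1) / 2
    mean(abs(w - mu) >= abs(sum(r[1:n]) - mu) - 1e-9)
  }
  identical_sides <- compare_accuracy(c(0.1, 0.1, 0.1), c(0.1, 0.1, 0.1))
  expect_equal(identical_sides$p_value, 1)

  sep <- compare_accuracy(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9))
  expect_equal(sep$p_value, oracle_p(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9)))
  expect_equal(sep$p_value, 0.1)
  expect_lt(sep$median_a, sep$median_b)

  set.seed(2)
  a <- runif(5); b <- runif(4) + 0.3
  expect_equal(compare_accuracy(a, b)$p_value, oracle_p(a, b))

  low <- compare_accuracy(0.4, c(0.1, 0.2, 0.3))
  expect_true(low$low_n)
  expect_error(compare_accuracy(c(NA_real_, NA_real_), c(0.1, 0.2)),
               "undefined")
})
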