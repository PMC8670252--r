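test_that("probe aggregation is the per-column mean, missing values ignored", {
  design <- experiment_design()
  vals <- matrix(2, nrow = 3, ncol = 8,
                 dimnames = list(c("p1", "p2", "p3"), design_columns(design)))
  vals["p2", ] <- 4
  vals["p3", ] <- 7
  tab <- expression_table(vals, design, "signal")
  pm <- data.frame(probe_id = c("p1", "p2", "p3"),
                   feature_id = c("fA", "fA", "fB"))
  agg <- aggregate_probes(tab, pm)
  expect_equal(unname(agg$values["fA", ]), rep(3, 8))   # mean(2, 4)
  expect_equal(unname(agg$values["fB", ]), rep(7, 8))   # single probe passthrough
  # missing ignored: {2, NA, 4} -> 3
  vals2 <- vals
  vals2["p2", 1] <- NA
  pm2 <- data.frame(probe_id = c("p1", "p2", "p3"), feature_id = "fA")
  agg2 <- aggregate_probes(expression_table(vals2, design, "signal"), pm2)
  expect_equal(unname(agg2$values["fA", 1]), mean(c(2, 7)))
})

test_that("aggregation is idempotent under the identity probe map", {
  tab <- make_signal_table(matrix(rnorm(16, 8), nrow = 2))
  pm <- data.frame(probe_id = rownames(tab$values),
                   feature_id = rownames(tab$values))
  agg <- aggregate_probes(tab, pm)
  expect_equal(agg$values, tab$values)
})

test_that("features with all probes missing in a column are dropped", {
  design <- experiment_design()
  vals <- matrix(5, 2, 8, dimnames = list(c("p1", "p2"), design_columns(design)))
  vals["p1", 3] <- NA
  pm <- data.frame(probe_id = c("p1", "p2"), feature_id = c("fA", "fB"))
  expect_message(agg <- aggregate_probes(expression_table(vals, design, "signal"), pm),
                 "dropped")
  expect_identical(rownames(agg$values), "fB")
})

test_that("fold changes follow the replicate-mean arithmetic", {
  # reference reps {5,5}, 0.5 h reps {7,7} -> log2fc 2; {5,6} vs {8,7} -> 2
  tab <- make_signal_table(rbind(
    c(5, 5, 7, 7, 5, 5, 5, 5),
    c(5, 6, 8, 7, 5.5, 5.5, 5.5, 5.5)
  ), ids = c("fA", "fB"))
  fc <- compute_fold_changes(tab)
  expect_equal(unname(fc$mean_fc$values["fA", "t0.5"]), 2)
  expect_equal(unname(fc$mean_fc$values["fB", "t0.5"]), 7.5 - 5.5)
  expect_equal(unname(fc$mean_fc$values["fA", c("t2", "t24")]), c(0, 0))
  # per-replicate fold changes subtract the reference replicate mean
  expect_equal(unname(fc$per_replicate_fc$values["fB", "t0.5_r1"]), 8 - 5.5)
  expect_equal(unname(fc$per_replicate_fc$values["fB", "t0.5_r2"]), 7 - 5.5)
})

test_that("swapping treated and reference negates every fold change", {
  set.seed(1)
  vals <- matrix(rnorm(40, 8), nrow = 5)
  tab <- make_signal_table(vals)
  fc <- compute_fold_changes(tab)
  # swap the reference and 24 h columns
  swapped <- vals[, c(7, 8, 3, 4, 5, 6, 1, 2)]
  tab2 <- make_signal_table(swapped, ids = rownames(tab$values))
  fc2 <- compute_fold_changes(tab2)
  expect_equal(fc2$mean_fc$values[, "t24"], -fc$mean_fc$values[, "t24"],
               tolerance = 1e-12)
})

test_that("missing reference propagates to missing fold changes", {
  vals <- rbind(c(NA, NA, 7, 7, 7, 7, 7, 7))
  tab <- make_signal_table(vals, ids = "fA")
  fc <- compute_fold_changes(tab)
  expect_true(all(is.na(fc$mean_fc$values["fA", ])))
})

test_that("DE status combines the fold-change and p-value gates", {
  tab <- make_signal_table(rbind(
    c(5.0, 5.1, 7.0, 7.1, 5.0, 5.1, 5.0, 5.1),   # clear 2-fold induction at 0.5 h
    c(6, 6, 6, 6, 6, 6, 6, 6)                     # identical everywhere
  ), ids = c("up1", "flat1"))
  fc <- compute_fold_changes(tab)
  de <- suppressMessages(call_differential(fc$mean_fc, tab))
  rec <- de[de$feature_id == "up1" & de$timepoint == 0.5, ]
  expect_identical(rec$status, "up")
  expect_lt(rec$p_value, 0.05)
  expect_equal(rec$log2fc, 2, tolerance = 1e-9)
  flat <- de[de$feature_id == "flat1", ]
  expect_true(all(flat$status == "unchanged"))
  expect_true(all(flat$p_value == 1))
})

test_that("a strong p-value cannot rescue a sub-threshold fold change", {
  tab <- make_signal_table(rbind(
    c(5.00, 5.01, 5.90, 5.91, 5.0, 5.01, 5.0, 5.01)  # log2fc 0.9, tiny variance
  ), ids = "f1")
  fc <- compute_fold_changes(tab)
  de <- suppressMessages(call_differential(fc$mean_fc, tab))
  rec <- de[de$timepoint == 0.5, ]
  expect_lt(rec$p_value, 0.05)
  expect_identical(rec$status, "unchanged")
})

test_that("Welch p-values match the textbook formula on random tables", {
  set.seed(7)
  for (i in 1:100) {
    x <- rnorm(3 + i %% 3, 8, 0.5)
    y <- rnorm(3 + (i + 1) %% 3, 8.5, 0.8)
    ours <- stats::t.test(x, y, var.equal = FALSE)$p.value
    expect_equal(ours, oracle_welch_p(x, y), tolerance = 1e-10)
  }
  # and the package path with test = "welch" reproduces them per feature
  tab <- make_signal_table(matrix(rnorm(80, 8), nrow = 10))
  fc <- compute_fold_changes(tab)
  de <- suppressMessages(call_differential(fc$mean_fc, tab, test = "welch"))
  for (f in rownames(tab$values)) {
    x <- tab$values[f, 3:4]; y <- tab$values[f, 1:2]
    expect_equal(de$p_value[de$feature_id == f & de$timepoint == 0.5],
                 oracle_welch_p(x, y), tolerance = 1e-10)
  }
})

test_that("pooled-test p-values equal the two-group ANOVA formula", {
  tab <- make_signal_table(matrix(rnorm(80, 8), nrow = 10))
  fc <- compute_fold_changes(tab)
  de <- suppressMessages(call_differential(fc$mean_fc, tab, test = "pooled"))
  for (f in rownames(tab$values)) {
    x <- tab$values[f, 3:4]; y <- tab$values[f, 1:2]
    expect_equal(de$p_value[de$feature_id == f & de$timepoint == 0.5],
                 oracle_anova2_p(x, y), tolerance = 1e-10)
  }
})

test_that("the clustering prefilter keeps exactly the moving features", {
  vals <- rbind(c(0.2, -0.5, 0.9), c(0.0, 1.0, 0.0), c(-1.4, 0.2, 0.1))
  rownames(vals) <- c("small", "boundary", "bigdown")
  colnames(vals) <- c("t0.5", "t2", "t24")
  tab <- expression_table(vals, NULL, "log2fc")
  kept <- suppressMessages(prefilter_for_clustering(tab, 1))
  expect_setequal(rownames(kept$values), c("boundary", "bigdown"))
  # brute-force agreement on random tables
  set.seed(11)
  for (i in 1:10) {
    v <- matrix(rnorm(60, 0, 0.8), nrow = 20,
                dimnames = list(sprintf("f%02d", 1:20), c("t0.5", "t2", "t24")))
    t2 <- expression_table(v, NULL, "log2fc")
    kept2 <- suppressMessages(prefilter_for_clustering(t2, 1))
    want <- rownames(v)[apply(abs(v), 1, max) >= 1]
    expect_setequal(rownames(kept2$values), want)
  }
})

test_that("noise-free DE calls equal the planted non-flat features", {
  cfg <- simulation_config(n_mrna = 30, n_asrna = 0, n_srna = 0,
                           n_pairs_inverse = 0, n_pairs_coregulated = 0,
                           noise_sd = 0, p_flat = 0.3, replicon_length = 50000,
                           seed = 21)
  fs <- simulate_annotation(cfg)
  tx <- simulate_transcriptome(fs, cfg)
  fc <- compute_fold_changes(tx$table)
  de <- suppressMessages(call_differential(fc$mean_fc, tx$table))
  called <- unique(de$feature_id[de$status != "unchanged"])
  planted <- tx$truth$clusters$feature_id[tx$truth$clusters$archetype != "flat"]
  expect_setequal(called, planted)
})
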