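test_that("opposite-strand overlaps pair and half-open adjacency does not", {
  fs <- feature_set(data.frame(
    feature_id = c("as1", "as2", "as3", "m1", "m2"),
    feature_type = c("asRNA", "asRNA", "asRNA", "mRNA", "mRNA"),
    replicon = "chr",
    start = c(100L, 100L, 380L, 150L, 200L),
    end = c(200L, 200L, 420L, 400L, 360L),
    strand = c("-", "-", "-", "+", "+"),
    stringsAsFactors = FALSE))
  # as1/as2 [100,200) vs m1 [150,400): overlap 50; vs m2 [200,360): adjacency
  # as3 [380,420) overlaps only the 3' end of m1 -> still a pair
  pairs <- find_antisense_pairs(fs)
  expect_equal(nrow(pairs), 3)
  p1 <- pairs[pairs$asrna_id == "as1", ]
  expect_identical(p1$mrna_id, "m1")
  expect_equal(p1$overlap_bp, 50L)
  expect_false(any(pairs$mrna_id == "m2"))
  expect_true(any(pairs$asrna_id == "as3" & pairs$mrna_id == "m1"))
})

test_that("same-strand overlaps and unstranded features never pair", {
  fs <- feature_set(data.frame(
    feature_id = c("as1", "as2", "m1"),
    feature_type = c("asRNA", "asRNA", "mRNA"),
    replicon = "chr",
    start = c(100L, 120L, 50L),
    end = c(200L, 220L, 300L),
    strand = c("+", ".", "+"),
    stringsAsFactors = FALSE))
  expect_equal(nrow(find_antisense_pairs(fs)), 0)
})

test_that("an asRNA spanning several genes yields one pair per mRNA", {
  fs <- feature_set(data.frame(
    feature_id = c("as1", "m1", "m2"),
    feature_type = c("asRNA", "mRNA", "mRNA"),
    replicon = "chr",
    start = c(100L, 50L, 400L),
    end = c(600L, 300L, 550L),
    strand = c("-", "+", "+"),
    stringsAsFactors = FALSE))
  pairs <- find_antisense_pairs(fs)
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$mrna_id, c("m1", "m2"))
})

test_that("random feature sets match the exhaustive pairwise scan", {
  set.seed(50)
  for (rep in 1:5) {
    n <- 120
    start <- sample.int(8000, n)
    fs <- feature_set(data.frame(
      feature_id = sprintf("f%03d", seq_len(n)),
      feature_type = sample(c("mRNA", "asRNA", "sRNA"), n, replace = TRUE),
      replicon = sample(c("chr", "pCA"), n, replace = TRUE),
      start = start, end = start + sample.int(500, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE))
    got <- find_antisense_pairs(fs)
    want <- oracle_antisense_pairs(fs)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("pair correlation behaves at the defined extremes", {
  v <- c(1.2, -0.5, 2.0, 0.3, -1.1, 0.8)
  expect_equal(pair_correlation(v, v), 1, tolerance = 1e-12)
  expect_equal(pair_correlation(v, -v), -1, tolerance = 1e-12)
  expect_equal(pair_correlation(1:6, 2 * (1:6)), 1, tolerance = 1e-12)
  expect_true(is.na(pair_correlation(v, rep(2, 6))))      # zero variance
  expect_true(is.na(pair_correlation(v, c(1, NA, 3, 4, 5, 6))))  # missing
  expect_error(pair_correlation(v, v[1:5]), "length mismatch")
  expect_error(pair_correlation(1:2, 2:1), ">= 3 points")
})

test_that("pair correlation matches the textbook formula on random vectors", {
  set.seed(51)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(pair_correlation(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("classification follows direction labels and the r threshold", {
  fcv <- rbind(
    asA = c(2, 2, 1, 1, 0.2, 0.2),       # induced shape
    mA  = -c(2, 2, 1, 1, 0.2, 0.2) + rnorm(6, 0, 0.05),
    asB = c(1, 1.1, 2, 2.1, 0.5, 0.4),
    mB  = c(1, 1.05, 2, 2.2, 0.5, 0.45)
  )
  colnames(fcv) <- c("t0.5_r1", "t0.5_r2", "t2_r1", "t2_r2", "t24_r1", "t24_r2")
  per_rep <- expression_table(fcv, NULL, "log2fc")
  pairs <- data.frame(asrna_id = c("asA", "asB"), mrna_id = c("mA", "mB"),
                      overlap_bp = c(40L, 60L), stringsAsFactors = FALSE)
  asn <- data.frame(feature_id = c("asA", "mA", "asB", "mB"),
                    cluster = c(1L, 3L, 2L, 2L),
                    direction = c("induced", "repressed", "induced", "induced"),
                    stringsAsFactors = FALSE)
  de <- data.frame(feature_id = rep(c("asA", "mA", "asB", "mB"), each = 1),
                   timepoint = 0.5, log2fc = c(2, -2, 1, 1),
                   p_value = 0.01, p_adjusted = 0.02,
                   status = c("up", "down", "up", "up"),
                   stringsAsFactors = FALSE)
  set.seed(52)
  rec <- classify_pairs(pairs, per_rep, asn, de, r_min = 0.65)
  expect_identical(rec$category[rec$asrna_id == "asA"], "as_up_m_down")
  expect_identical(rec$category[rec$asrna_id == "asB"], "both_up")
  # below-threshold correlation leaves the pair unclassified even if eligible
  rec2 <- classify_pairs(pairs, per_rep, asn, de, r_min = 0.9999999)
  expect_true(all(rec2$category == "unclassified"))
  expect_true(all(rec2$eligible))
})

test_that("missing cluster assignment or missing DE blocks eligibility", {
  fcv <- rbind(asA = c(2, 2, 1, 1, 0.2, 0.2), mA = c(2, 2.1, 1, 1.1, 0.2, 0.25))
  colnames(fcv) <- c("t0.5_r1", "t0.5_r2", "t2_r1", "t2_r2", "t24_r1", "t24_r2")
  per_rep <- expression_table(fcv, NULL, "log2fc")
  pairs <- data.frame(asrna_id = "asA", mrna_id = "mA", overlap_bp = 30L)
  de_ok <- data.frame(feature_id = c("asA", "mA"), timepoint = 0.5,
                      log2fc = 2, p_value = 0.01, p_adjusted = 0.02, status = "up")
  asn_na <- data.frame(feature_id = c("asA", "mA"), cluster = c(1L, NA),
                       direction = c("induced", NA))
  rec <- classify_pairs(pairs, per_rep, asn_na, de_ok)
  expect_false(rec$eligible)
  asn_ok <- data.frame(feature_id = c("asA", "mA"), cluster = 1L,
                       direction = "induced")
  de_flat <- de_ok; de_flat$status <- "unchanged"
  rec2 <- classify_pairs(pairs, per_rep, asn_ok, de_flat)
  expect_false(rec2$eligible)
  expect_identical(rec2$category, "unclassified")
})

test_that("random instances classify exactly like the rule-by-rule oracle", {
  set.seed(53)
  for (rep in 1:10) {
    n <- 20
    ids_as <- sprintf("as%02d", 1:n); ids_m <- sprintf("m%02d", 1:n)
    base <- matrix(rnorm(6 * n), nrow = n)
    corr_sign <- sample(c(-1, 1), n, replace = TRUE)
    jitter <- matrix(rnorm(6 * n, 0, sample(c(0.05, 2), n, replace = TRUE)),
                     nrow = n)
    fcv <- rbind(base, corr_sign * base + jitter)
    rownames(fcv) <- c(ids_m, ids_as)
    colnames(fcv) <- c("t0.5_r1", "t0.5_r2", "t2_r1", "t2_r2", "t24_r1", "t24_r2")
    per_rep <- expression_table(fcv, NULL, "log2fc")
    pairs <- data.frame(asrna_id = ids_as, mrna_id = ids_m,
                        overlap_bp = sample.int(100, n))
    dir_pool <- c("induced", "repressed")
    asn <- data.frame(
      feature_id = c(ids_as, ids_m),
      cluster = sample(c(1L, 2L, 3L, 4L, NA), 2 * n, replace = TRUE,
                       prob = c(0.22, 0.22, 0.22, 0.22, 0.12)))
    asn$direction <- ifelse(is.na(asn$cluster), NA_character_,
                            ifelse(asn$cluster <= 2, "induced", "repressed"))
    de <- data.frame(feature_id = c(ids_as, ids_m), timepoint = 0.5,
                     log2fc = 1, p_value = 0.01, p_adjusted = 0.02,
                     status = sample(c("up", "down", "unchanged"), 2 * n,
                                     replace = TRUE))
    rec <- classify_pairs(pairs, per_rep, asn, de, r_min = 0.65)
    r <- vapply(seq_len(n), function(i) {
      oracle_pearson(fcv[ids_as[i], ], fcv[ids_m[i], ])
    }, numeric(1))
    dirmap <- stats::setNames(asn$direction, asn$feature_id)
    clmap <- stats::setNames(asn$cluster, asn$feature_id)
    demap <- stats::setNames(de$status != "unchanged", de$feature_id)
    want <- oracle_classify(r,
                            dirmap[ids_as], dirmap[ids_m],
                            !is.na(clmap[ids_as]), !is.na(clmap[ids_m]),
                            demap[ids_as], demap[ids_m])
    expect_identical(rec$category, want)
    # counts conservation: eligible = classified + eligible with weak r
    summ <- attr(rec, "summary")
    expect_equal(sum(rec$eligible),
                 sum(summ$n[summ$category != "unclassified"]) +
                   sum(rec$eligible & rec$category == "unclassified"))
  }
})

test_that("negating asRNA profiles with flipped directions mirrors categories", {
  cfg <- simulation_config(n_mrna = 30, n_asrna = 10, n_srna = 0,
                           n_pairs_inverse = 5, n_pairs_coregulated = 5,
                           noise_sd = 0, p_flat = 0, replicon_length = 60000,
                           seed = 54)
  fs <- simulate_annotation(cfg)
  tx <- simulate_transcriptome(fs, cfg)
  fc <- compute_fold_changes(tx$table)
  de <- suppressMessages(call_differential(fc$mean_fc, tx$table))
  arch <- tx$truth$clusters
  asn <- data.frame(
    feature_id = arch$feature_id,
    cluster = as.integer(sub("cluster", "", arch$archetype)),
    direction = ifelse(arch$archetype %in% c("cluster1", "cluster2"),
                       "induced", "repressed"))
  pairs <- find_antisense_pairs(fs)
  rec <- classify_pairs(pairs, fc$per_replicate_fc, asn, de)
  # negate every asRNA profile and flip its cluster direction + DE status
  fcv2 <- fc$per_replicate_fc$values
  as_ids <- fs$feature_id[fs$feature_type == "asRNA"]
  fcv2[as_ids, ] <- -fcv2[as_ids, ]
  asn2 <- asn
  flip <- asn2$feature_id %in% as_ids
  asn2$direction[flip] <- ifelse(asn2$direction[flip] == "induced",
                                 "repressed", "induced")
  de2 <- de
  sw <- de2$feature_id %in% as_ids & de2$status != "unchanged"
  de2$status[sw] <- ifelse(de2$status[sw] == "up", "down", "up")
  rec2 <- classify_pairs(pairs, expression_table(fcv2, NULL, "log2fc"),
                         asn2, de2)
  swap <- c(as_up_m_down = "both_down", as_down_m_up = "both_up",
            both_up = "as_down_m_up", both_down = "as_up_m_down",
            unclassified = "unclassified")
  expect_identical(rec2$category, unname(swap[rec$category]))
})
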