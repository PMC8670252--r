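test_that("row standardization gives mean 0, sd 1 and is idempotent", {
  x <- matrix(c(1, 2, 3, 4,
                5, 5, 5, 5,
                2, 4, 8, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "const", "b"), NULL))
  expect_warning(z <- standardize_profiles(x), "zero-variance")
  expect_setequal(rownames(z), c("a", "b"))
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(standardize_profiles(z), z, tolerance = 1e-12)
})

test_that("rows with missing values are excluded with a message", {
  x <- matrix(rnorm(12), nrow = 3, dimnames = list(c("a", "b", "c"), NULL))
  x[2, 1] <- NA
  expect_message(z <- standardize_profiles(x), "incomplete")
  expect_setequal(rownames(z), c("a", "c"))
})

test_that("the fuzzifier closed form matches its published calibration", {
  expect_equal(round(estimate_fuzzifier(3831, 4), 2), 2.53)
  expect_equal(estimate_fuzzifier(3831, 3), 3.64, tolerance = 0.005)
  # strictly decreasing in D, always above 1
  for (N in c(100, 1000, 10000)) {
    ms <- vapply(2:10, function(D) estimate_fuzzifier(N, D), numeric(1))
    expect_true(all(diff(ms) < 0))
    expect_true(all(ms > 1))
  }
  expect_error(estimate_fuzzifier(1, 4), "N >= 2")
  # equals an independently coded evaluation over a grid
  for (N in c(50, 500, 3831)) {
    for (D in c(2, 4, 8)) {
      direct <- 1 + (1418 / N + 22.05) * D^(-2) +
        (12.33 / N + 0.243) * exp(log(D) * (-0.0406 * log(N) - 0.1134))
      expect_equal(estimate_fuzzifier(N, D), direct, tolerance = 1e-12)
    }
  }
})

test_that("fuzzy c-means separates well-separated groups with high membership", {
  set.seed(30)
  X <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
             matrix(rnorm(100, 5, 0.1), ncol = 2))
  fit <- fuzzy_cmeans(X, 2, m = 2, seed = 1)
  grp <- rep(1:2, each = 50)
  own <- vapply(seq_len(100), function(i) {
    max(fit$memberships[i, ])
  }, numeric(1))
  expect_true(all(own > 0.9))
  expect_true(fit$converged)
  hard <- max.col(fit$memberships)
  expect_true(abs(sum(hard[1:50] == hard[1]) - 50) == 0)
  expect_false(hard[1] == hard[51])
})

test_that("memberships agree with an independent implementation of the updates", {
  skip_if_not_installed("e1071")
  set.seed(31)
  for (i in 1:10) {
    n <- sample(30:100, 1)
    X <- rbind(matrix(rnorm(2 * ceiling(n / 2), 0, 0.3), ncol = 2),
               matrix(rnorm(2 * floor(n / 2), 4, 0.3), ncol = 2))
    rownames(X) <- sprintf("r%03d", seq_len(nrow(X)))
    fit <- fuzzy_cmeans(X, 2, m = 2, seed = i, tol = 1e-12)
    ref <- e1071::cmeans(X, centers = fit$centroids, m = 2,
                         iter.max = 500, method = "cmeans")
    expect_lt(max(abs(fit$memberships - ref$membership)), 1e-6)
  }
})

test_that("the objective is non-increasing and memberships stay normalized", {
  set.seed(32)
  for (i in 1:50) {
    X <- matrix(rnorm(40 * 3), ncol = 3)
    fit <- fuzzy_cmeans(X, sample(2:4, 1), m = runif(1, 1.3, 3), seed = i,
                        nstart = 1, max_iter = 60)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
    expect_equal(unname(rowSums(fit$memberships)), rep(1, 40), tolerance = 1e-9)
    expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
  }
})

test_that("a point coinciding with a centroid gets membership one", {
  X <- rbind(c(0, 0), c(0, 0), c(0, 0), c(6, 6), c(6, 6), c(6, 6))
  rownames(X) <- sprintf("p%d", 1:6)
  fit <- fuzzy_cmeans(X, 2, m = 2, seed = 1)
  # centroids converge onto the duplicated points themselves
  expect_equal(unname(apply(fit$memberships, 1, max)), rep(1, 6))
})

test_that("at m near 1 the solution matches k-means from the same start", {
  set.seed(33)
  X <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 2),
             matrix(rnorm(60, 3, 0.2), ncol = 2),
             matrix(rnorm(60, c(6, 0), 0.2), ncol = 2))
  rownames(X) <- sprintf("p%02d", 1:90)
  seed <- 5
  set.seed(seed)
  init <- X[sample.int(90, 3), , drop = FALSE]
  fit <- fuzzy_cmeans(X, 3, m = 1.05, seed = seed, nstart = 1)
  km <- stats::kmeans(X, centers = init)
  expect_true(all(apply(fit$memberships, 1, max) > 0.99))
  hard <- max.col(fit$memberships)
  # same partition (labels may permute)
  expect_equal(length(unique(paste(hard, km$cluster))), 3)
})

test_that("permuting input rows permutes memberships identically", {
  set.seed(34)
  X <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
             matrix(rnorm(40, 4, 0.2), ncol = 2))
  rownames(X) <- sprintf("p%02d", 1:40)
  perm <- sample.int(40)
  f1 <- fuzzy_cmeans(X, 2, m = 2, seed = 2, tol = 1e-12)
  f2 <- fuzzy_cmeans(X[perm, ], 2, m = 2, seed = 2, tol = 1e-12)
  # align cluster labels via centroid matching, then compare row-wise
  map <- apply(f2$centroids, 1, function(v) {
    which.min(colSums((t(f1$centroids) - v)^2))
  })
  expect_equal(unname(f2$memberships[rownames(X), map]),
               unname(f1$memberships), tolerance = 1e-6)
})

test_that("elbow selection recovers the planted cluster count", {
  cfg <- simulation_config(n_mrna = 400, n_asrna = 0, n_srna = 0,
                           n_pairs_inverse = 0, n_pairs_coregulated = 0,
                           p_flat = 0, noise_sd = 0.15, replicon_length = 4e5,
                           seed = 40)
  fs <- simulate_annotation(cfg)
  tx <- simulate_transcriptome(fs, cfg)
  X <- cluster_input(compute_fold_changes(tx$table)$mean_fc)
  sel <- select_cluster_count(X, estimate_fuzzifier(nrow(X), ncol(X)),
                              c_range = 2:8, seed = 1, nstart = 3)
  expect_equal(sel$c, 4)
  expect_equal(nrow(sel$curve), 7)
})

test_that("two planted groups yield c = 2 and a blob falls back to the minimum", {
  set.seed(41)
  X2 <- rbind(matrix(rnorm(200, 0, 0.15), ncol = 4),
              matrix(rnorm(200, 2, 0.15), ncol = 4))
  rownames(X2) <- sprintf("p%03d", 1:100)
  sel2 <- suppressWarnings(select_cluster_count(X2, 2, c_range = 2:8,
                                                seed = 1, nstart = 3))
  expect_equal(sel2$c, 2)
  blob <- matrix(rnorm(400), ncol = 4,
                 dimnames = list(sprintf("b%03d", 1:100), NULL))
  expect_warning(sel3 <- select_cluster_count(blob, 2, c_range = 2:8,
                                              seed = 1, nstart = 3),
                 "low confidence")
  expect_equal(sel3$c, 2)
})

test_that("elbow selection rejects ranges too short for a second difference", {
  X <- matrix(rnorm(80), ncol = 4, dimnames = list(sprintf("p%d", 1:20), NULL))
  expect_error(select_cluster_count(X, 2, c_range = 2:3), "3 candidates")
})

test_that("membership filters assign, rescue, or abstain as specified", {
  model <- structure(list(
    c = 4, m = 2.5,
    centroids = matrix(c(1, 0.5, -0.2, 0.1,
                         0.3, 1, 0.2, -0.1,
                         -1, -0.5, 0.2, -0.1,
                         -0.3, -1, -0.2, 0.1), nrow = 4, byrow = TRUE,
                       dimnames = list(paste0("cluster", 1:4), NULL)),
    memberships = matrix(c(0.7, 0.1, 0.1, 0.1,
                           0.35, 0.30, 0.20, 0.15,
                           0.30, 0.25, 0.25, 0.20), nrow = 3, byrow = TRUE,
                         dimnames = list(c("clear", "rescued", "weak"),
                                         paste0("cluster", 1:4))),
    objective = 0, converged = TRUE,
    direction = c(cluster1 = "induced", cluster2 = "induced",
                  cluster3 = "repressed", cluster4 = "repressed"),
    assignments = NULL), class = "cluster_model")
  model <- assign_clusters(model, membership_min = 0.5, combined_min = 0.6)
  a <- model$assignments
  expect_equal(unname(a["clear"]), 1L)     # 0.7 >= 0.5
  expect_equal(unname(a["rescued"]), 1L)   # 0.35 + 0.30 = 0.65 > 0.6
  expect_true(is.na(a["weak"]))            # 0.55 and 0.45 both <= 0.6
  tab <- assignment_table(model)
  expect_identical(tab$direction[tab$feature_id == "rescued"], "induced")
})

test_that("direction labels follow the dominant centroid entry", {
  cen <- rbind(c(0.2, 1.5, -0.4), c(-2, 0.3, 0.2))
  rownames(cen) <- c("c1", "c2")
  dirs <- saltomics:::centroid_directions(cen)
  expect_identical(unname(dirs), c("induced", "repressed"))
})
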