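# Shared fixtures and independent oracles, built in code at test time.

# small signal table under the default design (values chosen by hand)
make_signal_table <- function(values, ids = sprintf("f%02d", seq_len(nrow(values)))) {
  design <- experiment_design()
  m <- if (is.matrix(values)) values else matrix(values, nrow = length(ids), byrow = TRUE)
  dimnames(m) <- list(ids, design_columns(design))
  expression_table(m, design, "signal")
}

# two-feature annotation with one opposite-strand overlap
make_overlap_features <- function() {
  feature_set(data.frame(
    feature_id = c("gA", "as_gA"),
    feature_type = c("mRNA", "asRNA"),
    replicon = "chr",
    start = c(150L, 100L),
    end = c(400L, 200L),
    strand = c("+", "-"),
    gene_id = c("gA", "gA"),
    stringsAsFactors = FALSE
  ))
}

# textbook Pearson r (independent of stats::cor)
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# textbook Welch t-test p-value
oracle_welch_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

# textbook two-group one-way ANOVA p-value (explicit sums of squares)
oracle_anova2_p <- function(x, y) {
  g <- mean(c(x, y))
  ssb <- length(x) * (mean(x) - g)^2 + length(y) * (mean(y) - g)^2
  ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  df1 <- 1
  df2 <- length(x) + length(y) - 2
  f <- (ssb / df1) / (ssw / df2)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

# exhaustive hypergeometric upper tail via binomial coefficients
oracle_hyper_upper <- function(k, K, N, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# brute-force strand-aware overlap scan on half-open intervals
oracle_antisense_pairs <- function(fs) {
  out <- list()
  as_f <- fs[fs$feature_type == "asRNA" & fs$strand %in% c("+", "-"), ]
  m_f <- fs[fs$feature_type == "mRNA" & fs$strand %in% c("+", "-"), ]
  for (i in seq_len(nrow(as_f))) {
    for (j in seq_len(nrow(m_f))) {
      if (as_f$replicon[i] == m_f$replicon[j] &&
          as_f$strand[i] != m_f$strand[j] &&
          as_f$start[i] < m_f$end[j] && as_f$end[i] > m_f$start[j]) {
        out[[length(out) + 1]] <- data.frame(
          asrna_id = as_f$feature_id[i], mrna_id = m_f$feature_id[j],
          overlap_bp = min(as_f$end[i], m_f$end[j]) -
            max(as_f$start[i], m_f$start[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(asrna_id = character(), mrna_id = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$asrna_id, res$mrna_id), , drop = FALSE]
}

# independent rule-by-rule pair classification (mirrors the published rules,
# written as plain loops so it cannot share code with the implementation)
oracle_classify <- function(r, as_dir, m_dir, as_assigned, m_assigned,
                            as_de, m_de, r_min = 0.65) {
  n <- length(r)
  out <- character(n)
  for (i in seq_len(n)) {
    eligible <- as_assigned[i] && m_assigned[i] && as_de[i] && m_de[i]
    cat_i <- "unclassified"
    if (eligible && !is.na(r[i]) && abs(r[i]) >= r_min) {
      if (r[i] <= -r_min && as_dir[i] == "induced" && m_dir[i] == "repressed") {
        cat_i <- "as_up_m_down"
      }
      if (r[i] <= -r_min && as_dir[i] == "repressed" && m_dir[i] == "induced") {
        cat_i <- "as_down_m_up"
      }
      if (r[i] >= r_min && as_dir[i] == "induced" && m_dir[i] == "induced") {
        cat_i <- "both_up"
      }
      if (r[i] >= r_min && as_dir[i] == "repressed" && m_dir[i] == "repressed") {
        cat_i <- "both_down"
      }
    }
    out[i] <- cat_i
  }
  out
}

# expected quadrant of a planted pair, from the ground-truth archetypes
expected_quadrant <- function(as_arch, m_arch) {
  dir_of <- function(a) {
    ifelse(a %in% c("cluster1", "cluster2"), "induced", "repressed")
  }
  ad <- dir_of(as_arch); md <- dir_of(m_arch)
  ifelse(ad == "induced" & md == "repressed", "as_up_m_down",
         ifelse(ad == "repressed" & md == "induced", "as_down_m_up",
                ifelse(ad == "induced", "both_up", "both_down")))
}

# run simulate + the pair-relevant pipeline stages in memory and score
# planted-pair recovery against the ground truth
score_pair_recovery <- function(seed, noise_sd = 0.2) {
  cfg <- simulation_config(seed = seed, noise_sd = noise_sd)
  fs <- simulate_annotation(cfg)
  tx <- simulate_transcriptome(fs, cfg)
  fc <- compute_fold_changes(tx$table)
  de <- suppressMessages(call_differential(fc$mean_fc, tx$table))
  pre <- suppressMessages(prefilter_for_clustering(fc$mean_fc))
  X <- cluster_input(pre)
  model <- fuzzy_cmeans(X, 4, estimate_fuzzifier(nrow(X), ncol(X)), seed = seed)
  model <- assign_clusters(model)
  rec <- suppressMessages(classify_pairs(find_antisense_pairs(fs),
                                         fc$per_replicate_fc,
                                         assignment_table(model), de))
  truth <- tx$truth
  arch <- stats::setNames(truth$clusters$archetype, truth$clusters$feature_id)
  exp_cat <- expected_quadrant(arch[truth$pairs$asrna_id],
                               arch[truth$pairs$mrna_id])
  got <- rec$category[match(paste(truth$pairs$asrna_id, truth$pairs$mrna_id),
                            paste(rec$asrna_id, rec$mrna_id))]
  classified <- !is.na(got) & got != "unclassified"
  list(
    sensitivity = mean(!is.na(got) & got == exp_cat),
    fdr = if (any(classified)) mean(got[classified] != exp_cat[classified]) else 0,
    records = rec
  )
}
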