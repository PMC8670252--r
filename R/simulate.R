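#' Simulation configuration
#'
#' Parameters of the synthetic multi-omics generator. The generated data
#' emulate the structure of the real study: a four-time-point (0, 0.5, 2,
#' 24 h) transcriptome in duplicate hybridizations, four temporal archetype
#' shapes (transiently induced peaking at 0.5 h or 2 h, and their repressed
#' mirrors) plus flat profiles, opposite-strand overlapping asRNA:mRNA
#' pairs planted as inversely regulated or co-regulated, a four-fraction
#' proteome (total, soluble, membrane, debris) in four biological
#' replicates (pooled triplicates for debris) with planted fold changes and
#' lognormal noise, and a metabolome with a carnitine-style internal
#' standard whose per-sample injection factor the normalization must
#' cancel.
#'
#' @param n_mrna,n_asrna,n_srna feature counts
#' @param n_pairs_inverse,n_pairs_coregulated planted asRNA:mRNA pairs
#'   (their sum must not exceed `n_asrna`)
#' @param replicon_length length of the single pseudo-replicon (bp)
#' @param archetype_amplitude peak height of the temporal archetypes
#'   (log2 units, default 2)
#' @param p_flat probability that an unconstrained feature is flat
#' @param noise_sd transcriptome replicate noise (additive Gaussian on the
#'   log2 scale)
#' @param transcriptome_replicates hybridizations per time point (default 2)
#' @param proteome_replicates biological replicates per condition (default
#'   4; the debris fraction uses `debris_replicates`, default 3)
#' @param debris_replicates pooled debris measurements (default 3)
#' @param n_proteins proteins in the proteome tables
#' @param protein_fc_up,protein_fc_down planted linear fold changes
#' @param p_protein_up,p_protein_down fraction of proteins planted at each
#' @param proteome_cv coefficient of variation of the lognormal abundance
#'   noise (linear fmol scale)
#' @param n_redistribute proteins that shift between the soluble and
#'   membrane fractions under salt at constant total amount
#' @param n_single_peptide proteins identified by a single peptide (exercise
#'   the identification filter)
#' @param n_metabolites metabolites in the metabolome table
#' @param metabolite_fcs planted metabolite fold changes, recycled over
#'   metabolites
#' @param metabolome_cv lognormal noise CV for metabolite intensities
#' @param metabolome_replicates replicates per condition (default 3)
#' @param injection_sd log-scale spread of the per-sample injection factor
#' @param seed integer master seed
#' @return object of class `simulation_config` (a validated list)
#' @export
simulation_config <- function(n_mrna = 600, n_asrna = 150, n_srna = 50,
                              n_pairs_inverse = 50, n_pairs_coregulated = 50,
                              replicon_length = 200000,
                              archetype_amplitude = 2, p_flat = 0.3,
                              noise_sd = 0.3,
                              transcriptome_replicates = 2,
                              proteome_replicates = 4, debris_replicates = 3,
                              n_proteins = 500,
                              protein_fc_up = 2, protein_fc_down = 0.5,
                              p_protein_up = 0.1, p_protein_down = 0.1,
                              proteome_cv = 0.1, n_redistribute = 50,
                              n_single_peptide = 4,
                              n_metabolites = 20,
                              metabolite_fcs = c(3, 2, 1, 0.5, 0.33),
                              metabolome_cv = 0.05,
                              metabolome_replicates = 3,
                              injection_sd = 0.3,
                              seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_mrna", "n_asrna", "n_srna", "n_pairs_inverse",
              "n_pairs_coregulated", "n_proteins", "n_metabolites")
  for (k in counts) if (cfg[[k]] < 0) stop("simulation_config: ", k, " must be >= 0")
  if (cfg$noise_sd < 0) stop("simulation_config: noise_sd must be >= 0")
  if (cfg$n_pairs_inverse + cfg$n_pairs_coregulated > cfg$n_asrna) {
    stop("simulation_config: planted pairs exceed n_asrna")
  }
  if (any(cfg$metabolite_fcs <= 0)) stop("simulation_config: metabolite_fcs must be > 0")
  class(cfg) <- "simulation_config"
  cfg
}

#' Temporal archetype profiles
#'
#' Piecewise log2 fold-change shapes over the sampling times (0, 0.5, 2,
#' 24 h): cluster1 peaks at 0.5 h and has largely decayed by 24 h, cluster2
#' peaks at 2 h; cluster3/cluster4 are their repressed mirror images; flat
#' is identically zero. Amplitudes scale with `amplitude`.
#'
#' @param amplitude peak height in log2 units (default 2)
#' @return named list of length-4 numeric profiles
#' @export
archetype_profiles <- function(amplitude = 2) {
  a <- amplitude
  list(
    cluster1 = c(0, a, 0.6 * a, 0.1 * a),
    cluster2 = c(0, 0.5 * a, a, 0.3 * a),
    cluster3 = c(0, -a, -0.6 * a, -0.1 * a),
    cluster4 = c(0, -0.5 * a, -a, -0.3 * a),
    flat = c(0, 0, 0, 0)
  )
}

# mirror partner under sign flip (inverse regulation)
mirror_archetype <- function(arch) {
  c(cluster1 = "cluster3", cluster2 = "cluster4",
    cluster3 = "cluster1", cluster4 = "cluster2", flat = "flat")[arch]
}

#' Simulate the genome annotation
#'
#' All features live on one pseudo-replicon, laid out in disjoint slots so
#' that only the planted pairs produce opposite-strand asRNA:mRNA overlaps:
#' mRNAs sit on the plus strand, each in its own slot; the first
#' `n_pairs_inverse + n_pairs_coregulated` mRNAs host an antisense RNA on
#' the minus strand overlapping them by construction; the remaining asRNAs
#' and all sRNAs occupy slots of their own and overlap nothing. The planted
#' pair table is attached as attribute `pair_truth`.
#'
#' @param config simulation_config
#' @return feature_set with attribute `pair_truth` (asrna_id, mrna_id,
#'   category in "inverse"/"coregulated")
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_pairs <- config$n_pairs_inverse + config$n_pairs_coregulated
  n_free_as <- config$n_asrna - n_pairs
  n_slots <- config$n_mrna + n_free_as + config$n_srna
  if (n_slots == 0) {
    fs <- feature_set(data.frame(feature_id = character(), feature_type = character(),
                                 replicon = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 gene_id = character(), stringsAsFactors = FALSE))
    attr(fs, "pair_truth") <- data.frame(asrna_id = character(), mrna_id = character(),
                                         category = character(), stringsAsFactors = FALSE)
    return(fs)
  }
  slot_len <- floor(config$replicon_length / n_slots)
  if (slot_len < 150) {
    stop("simulate_annotation: infeasible packing (", n_slots,
         " features need > ", n_slots * 150, " bp, replicon has ",
         config$replicon_length, ")")
  }
  slot_start <- (seq_len(n_slots) - 1L) * slot_len
  rows <- list()
  slot <- 1L
  # mRNAs: plus strand, one per slot with a margin so slots never touch
  for (i in seq_len(config$n_mrna)) {
    len <- floor(stats::runif(1, 0.5, 0.85) * (slot_len - 20))
    st <- slot_start[slot] + 10L
    rows[[length(rows) + 1]] <- data.frame(
      feature_id = sprintf("g%04d", i), feature_type = "mRNA",
      replicon = "chr", start = st, end = st + len, strand = "+",
      gene_id = sprintf("g%04d", i), stringsAsFactors = FALSE)
    slot <- slot + 1L
  }
  # planted asRNAs: minus strand, nested inside their host mRNA
  pair_truth <- data.frame(asrna_id = character(), mrna_id = character(),
                           category = character(), stringsAsFactors = FALSE)
  if (n_pairs > 0) {
    for (i in seq_len(n_pairs)) {
      host <- rows[[i]]
      span <- host$end - host$start
      as_len <- max(30L, floor(stats::runif(1, 0.3, 0.7) * span))
      offset <- floor(stats::runif(1, 0, span - as_len))
      rows[[length(rows) + 1]] <- data.frame(
        feature_id = sprintf("as_%s", host$feature_id), feature_type = "asRNA",
        replicon = "chr", start = host$start + offset,
        end = host$start + offset + as_len, strand = "-",
        gene_id = host$feature_id, stringsAsFactors = FALSE)
      pair_truth <- rbind(pair_truth, data.frame(
        asrna_id = sprintf("as_%s", host$feature_id), mrna_id = host$feature_id,
        category = if (i <= config$n_pairs_inverse) "inverse" else "coregulated",
        stringsAsFactors = FALSE))
    }
  }
  # free asRNAs: own slot, minus strand, no mRNA to overlap
  for (j in seq_len(n_free_as)) {
    len <- floor(stats::runif(1, 0.3, 0.6) * (slot_len - 20))
    st <- slot_start[slot] + 10L
    rows[[length(rows) + 1]] <- data.frame(
      feature_id = sprintf("as_free%03d", j), feature_type = "asRNA",
      replicon = "chr", start = st, end = st + len, strand = "-",
      gene_id = NA_character_, stringsAsFactors = FALSE)
    slot <- slot + 1L
  }
  # sRNAs: own slot, plus strand
  for (j in seq_len(config$n_srna)) {
    len <- floor(stats::runif(1, 0.2, 0.4) * (slot_len - 20))
    st <- slot_start[slot] + 10L
    rows[[length(rows) + 1]] <- data.frame(
      feature_id = sprintf("ncr%03d", j), feature_type = "sRNA",
      replicon = "chr", start = st, end = st + len, strand = "+",
      gene_id = NA_character_, stringsAsFactors = FALSE)
    slot <- slot + 1L
  }
  fs <- feature_set(do.call(rbind, rows))
  attr(fs, "pair_truth") <- pair_truth
  fs
}

#' Simulate the transcriptome time course
#'
#' Per-replicate log2 signals are baseline + archetype profile + Gaussian
#' noise. Unconstrained features draw their archetype at random (flat with
#' probability `p_flat`); planted inverse pairs give the asRNA the
#' sign-flipped archetype of its host mRNA, co-regulated pairs share the
#' host's archetype, and pair hosts are never flat (a flat pair would have
#' no regulation to recover).
#'
#' @param features feature_set from [simulate_annotation()]
#' @param config simulation_config
#' @param archetype_assignment optional named character vector
#'   (feature_id -> archetype) overriding the random assignment
#' @return list: `table` (signal expression_table), `truth` (list with
#'   `clusters` data.frame feature_id/archetype and `pairs` the planted
#'   pair table)
#' @export
simulate_transcriptome <- function(features, config, archetype_assignment = NULL) {
  stopifnot(inherits(features, "feature_set"), inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  design <- experiment_design(c(0, 0.5, 2, 24), config$transcriptome_replicates)
  profiles <- archetype_profiles(config$archetype_amplitude)
  pair_truth <- attr(features, "pair_truth")
  ids <- features$feature_id

  arch <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(archetype_assignment)) {
    arch[names(archetype_assignment)] <- archetype_assignment
  }
  clustered <- c("cluster1", "cluster2", "cluster3", "cluster4")
  hosts <- if (is.null(pair_truth)) character() else pair_truth$mrna_id
  paired_as <- if (is.null(pair_truth)) character() else pair_truth$asrna_id
  free <- setdiff(ids[is.na(arch)], c(hosts, paired_as))
  arch[free] <- sample(c(clustered, "flat"), length(free), replace = TRUE,
                       prob = c(rep((1 - config$p_flat) / 4, 4), config$p_flat))
  need_host <- intersect(hosts, ids[is.na(arch)])
  arch[need_host] <- sample(clustered, length(need_host), replace = TRUE)
  if (length(paired_as) > 0) {
    for (i in seq_len(nrow(pair_truth))) {
      a <- pair_truth$asrna_id[i]
      if (!is.na(arch[a])) next
      host_arch <- arch[pair_truth$mrna_id[i]]
      arch[a] <- if (pair_truth$category[i] == "inverse") {
        mirror_archetype(host_arch)
      } else {
        host_arch
      }
    }
  }

  cols <- design_columns(design)
  vals <- matrix(NA_real_, length(ids), length(cols), dimnames = list(ids, cols))
  baseline <- stats::runif(length(ids), 6, 12)
  prof <- t(vapply(arch, function(a) profiles[[a]], numeric(4)))
  for (ti in seq_along(design$timepoints)) {
    for (r in seq_len(design$replicates)) {
      col <- sprintf("t%s_r%d", fmt_tp(design$timepoints[ti]), r)
      vals[, col] <- baseline + prof[, ti] +
        stats::rnorm(length(ids), 0, config$noise_sd)
    }
  }
  list(
    table = expression_table(vals, design, "signal"),
    truth = list(
      clusters = data.frame(feature_id = ids, archetype = unname(arch),
                            stringsAsFactors = FALSE),
      pairs = pair_truth
    )
  )
}

#' Simulate the fractionated proteome
#'
#' Each protein gets a control total amount (lognormal around 50 fmol) and
#' a per-fraction distribution (soluble/membrane shares plus a small debris
#' share) summing to 1. Salt amounts are control x planted fold change,
#' and a configurable subset of proteins additionally swaps part of its
#' soluble share into the membrane fraction under salt at constant total
#' (the redistribution scenario the weighted fold change is designed for).
#' All replicate measurements carry lognormal noise at the configured CV;
#' the debris fraction has its own (pooled) replicate count. A small
#' peptide-level table for one control run is included for Hi3 testing,
#' with a spiked standard protein at known fmol.
#'
#' @param config simulation_config
#' @param protein_ids optional ids (default `g0001..`, matching the
#'   simulated mRNA locus tags so omics layers can be joined)
#' @param true_fc optional vector of planted linear fold changes, one per
#'   protein; by default the configured pattern (`p_protein_up` at
#'   `protein_fc_up`, `p_protein_down` at `protein_fc_down`, the rest at 1)
#'   is planted at random positions. [simulate_all()] instead passes fold
#'   changes derived from the planted 24 h transcript changes so the omics
#'   layers are genuinely correlated.
#' @return list: `quants` (long data.frame: protein_id, fraction, condition,
#'   replicate, amount_fmol, n_unique_peptides), `peptides` (protein_id,
#'   peptide_id, intensity; standard protein "HI3_STD"), `truth`
#'   (protein_id, true_fc, redistributed, true_total_control_fmol)
#' @export
simulate_proteome <- function(config, protein_ids = NULL, true_fc = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  n <- config$n_proteins
  if (is.null(protein_ids)) protein_ids <- sprintf("g%04d", seq_len(n))
  stopifnot(length(protein_ids) == n)
  if (is.null(true_fc)) {
    n_up <- round(config$p_protein_up * n)
    n_down <- round(config$p_protein_down * n)
    true_fc <- rep(1, n)
    planted <- sample.int(n, n_up + n_down)
    true_fc[planted[seq_len(n_up)]] <- config$protein_fc_up
    if (n_down > 0) true_fc[planted[n_up + seq_len(n_down)]] <- config$protein_fc_down
  }
  stopifnot(length(true_fc) == n, all(true_fc > 0))

  p_deb <- stats::runif(n, 0.05, 0.15)
  sol_share <- stats::runif(n, 0.25, 0.75)
  p_sol <- (1 - p_deb) * sol_share
  p_mem <- (1 - p_deb) * (1 - sol_share)
  # salt-condition distribution: redistributed proteins move half their
  # soluble share into the membrane fraction; totals are untouched
  redistributed <- rep(FALSE, n)
  if (config$n_redistribute > 0) {
    redistributed[sample.int(n, min(config$n_redistribute, n))] <- TRUE
  }
  p_sol_salt <- ifelse(redistributed, 0.5 * p_sol, p_sol)
  p_mem_salt <- ifelse(redistributed, p_mem + 0.5 * p_sol, p_mem)

  total_control <- stats::rlnorm(n, log(50), 0.5)
  cv <- config$proteome_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- function(k) {
    if (sdlog == 0) rep(1, k) else stats::rlnorm(k, -sdlog^2 / 2, sdlog)
  }
  npep <- sample(2:25, n, replace = TRUE)
  if (config$n_single_peptide > 0) {
    npep[sample.int(n, min(config$n_single_peptide, n))] <- 1L
  }

  frac_shares <- list(
    control = list(total = rep(1, n), soluble = p_sol, membrane = p_mem, debris = p_deb),
    salt = list(total = rep(1, n), soluble = p_sol_salt, membrane = p_mem_salt,
                debris = p_deb)
  )
  rows <- list()
  for (cond in c("control", "salt")) {
    base <- if (cond == "salt") total_control * true_fc else total_control
    for (fr in c("total", "soluble", "membrane", "debris")) {
      n_rep <- if (fr == "debris") config$debris_replicates else config$proteome_replicates
      mu <- base * frac_shares[[cond]][[fr]]
      for (r in seq_len(n_rep)) {
        rows[[length(rows) + 1]] <- data.frame(
          protein_id = protein_ids, fraction = fr, condition = cond,
          replicate = r, amount_fmol = mu * noise(n),
          n_unique_peptides = npep, stringsAsFactors = FALSE)
      }
    }
  }
  quants <- do.call(rbind, rows)

  # peptide table: one control run over the first (up to) 20 proteins plus
  # the standard; scaled so the top-3 mean encodes the true fmol exactly
  std_signal <- 1e5
  pep_rows <- list(data.frame(
    protein_id = "HI3_STD", peptide_id = sprintf("std_p%d", 1:5),
    intensity = std_signal * c(1.2, 1.0, 0.8, 0.5, 0.3) / 1.0,
    stringsAsFactors = FALSE))
  std_top3 <- mean(sort(pep_rows[[1]]$intensity, decreasing = TRUE)[1:3])
  hi3_fmol <- 40
  for (i in seq_len(min(20, n))) {
    k <- sample(3:6, 1)
    shape <- sort(stats::runif(k, 0.3, 1.5), decreasing = TRUE)
    target <- total_control[i] / hi3_fmol * std_top3
    shape <- shape / mean(shape[1:3]) * target
    pep_rows[[length(pep_rows) + 1]] <- data.frame(
      protein_id = protein_ids[i], peptide_id = sprintf("%s_p%d", protein_ids[i], seq_len(k)),
      intensity = shape, stringsAsFactors = FALSE)
  }
  list(
    quants = quants,
    peptides = do.call(rbind, pep_rows),
    truth = data.frame(protein_id = protein_ids, true_fc = true_fc,
                       redistributed = redistributed,
                       true_total_control_fmol = total_control,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate the metabolome with an internal standard
#'
#' Raw intensities are true abundance x per-sample injection factor x
#' lognormal noise; the internal-standard channel of the same sample
#' carries the identical injection factor (and its own measurement noise),
#' so dividing by it cancels the injection factor exactly. Salt abundances
#' are control x planted fold change.
#'
#' @param config simulation_config
#' @return list: `measurements` (metabolite_id, condition, replicate,
#'   intensity, standard_intensity), `truth` (metabolite_id, true_fc)
#' @export
simulate_metabolome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 3L)
  n <- config$n_metabolites
  ids <- sprintf("met%02d", seq_len(n))
  true_fc <- rep_len(config$metabolite_fcs, n)
  abundance <- stats::runif(n, 0.5, 5)
  cv <- config$metabolome_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- function(k) if (sdlog == 0) rep(1, k) else stats::rlnorm(k, -sdlog^2 / 2, sdlog)
  std_base <- 1e5
  rows <- list()
  for (cond in c("control", "salt")) {
    level <- if (cond == "salt") abundance * true_fc else abundance
    for (r in seq_len(config$metabolome_replicates)) {
      inj <- exp(stats::rnorm(1, 0, config$injection_sd))
      rows[[length(rows) + 1]] <- data.frame(
        metabolite_id = ids, condition = cond, replicate = r,
        intensity = level * inj * std_base * noise(n) / 100,
        standard_intensity = std_base * inj * noise(n),
        stringsAsFactors = FALSE)
    }
  }
  list(
    measurements = do.call(rbind, rows),
    truth = data.frame(metabolite_id = ids, true_fc = true_fc,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate the KO-term annotation
#'
#' Each mRNA gene receives one to three terms from a generic pool; in
#' addition, one planted term per archetype cluster is given to most of
#' that cluster's genes and only rarely to others, so the planted term is
#' genuinely over-represented in its cluster.
#'
#' @param cluster_truth data.frame (feature_id, archetype) for mRNA genes
#' @param config simulation_config
#' @return data.frame: gene_id, ko_term
#' @export
simulate_ko_annotation <- function(cluster_truth, config) {
  set.seed(config$seed + 4L)
  genes <- cluster_truth$feature_id
  pool <- sprintf("KO%04d", 1:30)
  rows <- list()
  for (g in genes) {
    k <- sample(1:3, 1)
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = g, ko_term = sample(pool, k), stringsAsFactors = FALSE)
  }
  for (cl in c("cluster1", "cluster2", "cluster3", "cluster4")) {
    term <- sprintf("KO_SALT_%s", sub("cluster", "", cl))
    members <- genes[cluster_truth$archetype == cl]
    others <- genes[cluster_truth$archetype != cl]
    pick_m <- members[stats::runif(length(members)) < 0.7]
    pick_o <- others[stats::runif(length(others)) < 0.02]
    picked <- c(pick_m, pick_o)
    if (length(picked) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = picked, ko_term = term, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out[order(out$gene_id, out$ko_term), , drop = FALSE]
}

file_checksum <- function(path) {
  sha <- Sys.which("sha256sum")
  if (nzchar(sha)) {
    strsplit(system2(sha, shQuote(path), stdout = TRUE), " ")[[1]][1]
  } else {
    unname(tools::md5sum(path))
  }
}

#' Generate and write the full synthetic input bundle
#'
#' Writes the GFF3 annotation, transcriptome signal table, four proteome
#' fraction tables, peptide table, metabolome table, KO annotation, two
#' "external" transcriptome fold-change tables (independent noisy
#' realizations of the planted 24 h fold changes, for the consensus
#' filter), the ground-truth tables, and a manifest of (role, path,
#' checksum). Identical (config, seed) produce bit-identical files.
#'
#' @param config simulation_config
#' @param out_dir output directory (created if missing)
#' @return data.frame manifest (role, path, sha256), invisibly the paths
#'   are all under `out_dir`
#' @export
simulate_all <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  fs <- simulate_annotation(config)
  write_annotation(fs, p("annotation.gff3"))
  tx <- simulate_transcriptome(fs, config)
  write_table(tx$table, p("transcriptome_signals.tsv"), digits = 8)
  write_table(tx$truth$clusters, p("truth_clusters.tsv"))
  write_table(tx$truth$pairs, p("truth_pairs.tsv"))

  # protein truth follows the planted 24 h transcript change of the same
  # locus tag, so the transcriptome and proteome layers correlate
  profiles0 <- archetype_profiles(config$archetype_amplitude)
  n_prot <- min(config$n_proteins, config$n_mrna)
  prot_ids <- sprintf("g%04d", seq_len(n_prot))
  arch_of <- stats::setNames(tx$truth$clusters$archetype, tx$truth$clusters$feature_id)
  prot_fc <- 2^vapply(arch_of[prot_ids], function(a) profiles0[[a]][4], numeric(1))
  cfg_prot <- config
  cfg_prot$n_proteins <- n_prot
  prot <- simulate_proteome(cfg_prot, protein_ids = prot_ids, true_fc = prot_fc)
  for (fr in c("total", "soluble", "membrane", "debris")) {
    write_table(prot$quants[prot$quants$fraction == fr, , drop = FALSE],
                p(sprintf("proteome_%s.tsv", fr)), digits = 8)
  }
  write_table(prot$peptides, p("proteome_peptides.tsv"), digits = 8)
  write_table(prot$truth, p("truth_proteins.tsv"), digits = 8)

  met <- simulate_metabolome(config)
  write_table(met$measurements, p("metabolome_intensities.tsv"), digits = 8)
  write_table(met$truth, p("truth_metabolites.tsv"))

  mrna_truth <- tx$truth$clusters[tx$truth$clusters$feature_id %in%
                                    fs$feature_id[fs$feature_type == "mRNA"], ]
  ko <- simulate_ko_annotation(mrna_truth, config)
  write_table(ko, p("ko_annotation.tsv"))

  # external transcriptome datasets: independent noisy views of the same
  # planted 24 h fold changes
  set.seed(config$seed + 5L)
  profiles <- archetype_profiles(config$archetype_amplitude)
  true24 <- vapply(mrna_truth$archetype, function(a) profiles[[a]][4], numeric(1))
  for (e in 1:2) {
    ext <- data.frame(gene_id = mrna_truth$feature_id,
                      log2fc = true24 + stats::rnorm(nrow(mrna_truth), 0, 0.2),
                      stringsAsFactors = FALSE)
    write_table(ext, p(sprintf("external_transcriptome_%d.tsv", e)), digits = 8)
  }

  files <- c(annotation = "annotation.gff3",
             transcriptome = "transcriptome_signals.tsv",
             truth_clusters = "truth_clusters.tsv",
             truth_pairs = "truth_pairs.tsv",
             proteome_total = "proteome_total.tsv",
             proteome_soluble = "proteome_soluble.tsv",
             proteome_membrane = "proteome_membrane.tsv",
             proteome_debris = "proteome_debris.tsv",
             proteome_peptides = "proteome_peptides.tsv",
             truth_proteins = "truth_proteins.tsv",
             metabolome = "metabolome_intensities.tsv",
             truth_metabolites = "truth_metabolites.tsv",
             ko_annotation = "ko_annotation.tsv",
             external_transcriptome_1 = "external_transcriptome_1.tsv",
             external_transcriptome_2 = "external_transcriptome_2.tsv")
  manifest <- data.frame(
    role = names(files),
    path = unname(files),
    sha256 = vapply(unname(files), function(f) file_checksum(p(f)), character(1)),
    stringsAsFactors = FALSE
  )
  write_table(manifest, p("manifest.tsv"))
  manifest
}
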