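#' Run the full analysis pipeline on a simulated (or compatible) input bundle
#'
#' Executes every stage in order on the files written by [simulate_all()]
#' (or any directory with the same layout): fold-change computation and
#' differential-expression calls, the clustering prefilter, fuzzifier
#' estimation and fuzzy c-means with membership-based assignment,
#' antisense-pair detection and classification, proteome fold changes and
#' differential calls, transcript/protein matching, cross-omics
#' correlation, the four-dataset consensus filter, KO-term enrichment, and
#' internal-standard metabolite normalization. All stage outputs are
#' written as TSV under `out_dir`.
#'
#' @param in_dir directory holding the input bundle
#' @param out_dir output directory (created if missing)
#' @param config analysis configuration (see [default_config()])
#' @param seed seed for clustering initialization
#' @param cluster_c "auto" for elbow selection, or a fixed integer
#' @return (invisibly) a list with every stage result
#' @export
run_all <- function(in_dir, out_dir, config = default_config(), seed = 1,
                    cluster_c = "auto") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p_in <- function(f) file.path(in_dir, f)
  p_out <- function(f) file.path(out_dir, f)
  design <- experiment_design()

  fs <- read_annotation(p_in("annotation.gff3"))
  signals <- read_expression(p_in("transcriptome_signals.tsv"), design)

  fc <- compute_fold_changes(signals, design)
  write_table(fc$mean_fc, p_out("fold_changes.tsv"))
  write_table(fc$per_replicate_fc, p_out("per_replicate_fc.tsv"))

  de <- call_differential(fc$mean_fc, signals, design,
                          lfc_min = config$de_lfc_min, alpha = config$de_alpha,
                          test = config$de_test)
  write_table(de, p_out("de_records.tsv"))

  pre <- prefilter_for_clustering(fc$mean_fc, config$cluster_prefilter_lfc)
  X <- cluster_input(pre)
  m <- estimate_fuzzifier(nrow(X), ncol(X))
  if (identical(cluster_c, "auto")) {
    sel <- select_cluster_count(X, m,
                                c_range = config$c_range_min:config$c_range_max,
                                seed = seed)
    write_table(sel$curve, p_out("elbow_curve.tsv"))
    cc <- sel$c
  } else {
    cc <- as.integer(cluster_c)
  }
  model <- fuzzy_cmeans(X, cc, m, seed = seed, tol = config$fcm_tol,
                        max_iter = config$fcm_max_iter,
                        nstart = config$fcm_nstart)
  model <- assign_clusters(model, config$membership_min,
                           config$combined_membership_min)
  asn <- assignment_table(model)
  memberships <- data.frame(feature_id = rownames(model$memberships),
                            model$memberships,
                            cluster = unname(model$assignments),
                            check.names = FALSE, stringsAsFactors = FALSE)
  write_table(memberships, p_out("cluster_memberships.tsv"))
  write_table(data.frame(cluster = rownames(model$centroids), model$centroids,
                         direction = unname(model$direction),
                         check.names = FALSE, stringsAsFactors = FALSE),
              p_out("centroids.tsv"))

  pairs <- find_antisense_pairs(fs)
  pair_records <- classify_pairs(pairs, fc$per_replicate_fc, asn, de,
                                 r_min = config$pair_r_min)
  write_table(pair_records, p_out("pair_records.tsv"))
  write_table(attr(pair_records, "summary"), p_out("pair_summary.tsv"))

  quants <- do.call(rbind, lapply(c("total", "soluble", "membrane", "debris"),
                                  function(fr) read_table(p_in(sprintf("proteome_%s.tsv", fr)))))
  pfc <- proteome_fold_changes(quants,
                               min_peptides = config$protein_min_peptides,
                               debris_weight = config$debris_weight,
                               scale = config$combined_fc_scale)
  prot <- call_differential_proteins(quants, pfc,
                                     fc_min = config$protein_fc_min,
                                     alpha = config$protein_alpha,
                                     test_fraction = config$protein_test_fraction,
                                     log_scale = config$protein_test_log)
  write_table(prot, p_out("protein_fold_changes.tsv"))

  # match on protein-coding transcripts only: asRNAs share their host's
  # locus tag and must not collide with it in the join
  mrna <- fs[fs$feature_type == "mRNA", , drop = FALSE]
  id_map <- data.frame(feature_id = mrna$feature_id, gene_id = mrna$gene_id,
                       stringsAsFactors = FALSE)
  matched <- match_transcript_protein(de, prot, id_map = id_map, timepoint = 24,
                                      similar_log2_max = config$similar_log2_max)
  write_table(matched$matches, p_out("omics_matches.tsv"))
  r <- cross_omics_correlation(matched$matches)
  write_table(data.frame(statistic = c("pearson_r", "n_matches", "n_similar"),
                         value = c(r, nrow(matched$matches),
                                   sum(matched$matches$similar))),
              p_out("correlation_summary.tsv"))

  own24 <- matched$matches[, c("gene_id", "transcript_log2fc")]
  names(own24) <- c("gene_id", "log2fc")
  de24 <- de[de$timepoint == 24, , drop = FALSE]
  de24$gene_id <- id_map$gene_id[match(de24$feature_id, id_map$feature_id)]
  own_full <- data.frame(gene_id = de24$gene_id, log2fc = de24$log2fc,
                         stringsAsFactors = FALSE)
  own_full <- own_full[!is.na(own_full$gene_id), ]
  ext1 <- read_table(p_in("external_transcriptome_1.tsv"))
  ext2 <- read_table(p_in("external_transcriptome_2.tsv"))
  prot_tab <- data.frame(gene_id = prot$protein_id,
                         log2fc = log2(prot$fc_combined),
                         stringsAsFactors = FALSE)
  consensus <- consensus_filter(list(own_full, ext1, ext2), prot_tab,
                                t_thresh = config$consensus_t_thresh,
                                p_thresh = config$consensus_p_thresh)
  write_table(consensus$records, p_out("consensus_genes.tsv"))

  ko <- read_table(p_in("ko_annotation.tsv"))
  mrna_asn <- asn[asn$feature_id %in% fs$feature_id[fs$feature_type == "mRNA"], ]
  enrich <- ko_enrichment(mrna_asn, ko)
  write_table(enrich, p_out("enrichment.tsv"))

  met <- read_table(p_in("metabolome_intensities.tsv"))
  met_fc <- metabolite_fold_changes(normalize_to_standard(met))
  write_table(met_fc, p_out("metabolite_fold_changes.tsv"))

  invisible(list(
    features = fs, signals = signals, fold_changes = fc, de = de,
    cluster_model = model, assignments = asn, fuzzifier = m, c = cc,
    pair_records = pair_records, protein_fold_changes = prot,
    matches = matched, cross_omics_r = r, consensus = consensus,
    enrichment = enrich, metabolite_fold_changes = met_fc
  ))
}
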