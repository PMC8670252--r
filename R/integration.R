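#' Match transcript and protein fold changes by locus tag
#'
#' Inner join of the 24 h transcript log2 fold changes with the combined
#' protein fold changes (converted to log2), keyed by locus tag. A matched
#' pair counts as "similar" when the two log2 changes differ by less than
#' log2(1.5). Genes present in only one omics layer are returned in side
#' lists; duplicate locus tags keep the first record with a message.
#'
#' @param de_records data.frame from [call_differential()] (the time point
#'   of interest is selected via `timepoint`)
#' @param protein_fc data.frame from [proteome_fold_changes()] or
#'   [call_differential_proteins()]
#' @param id_map optional data.frame (feature_id, gene_id) mapping transcript
#'   features to locus tags; when NULL the feature_id is used directly
#' @param timepoint transcript time point to match (default 24)
#' @param similar_log2_max similarity threshold on |delta log2| (default
#'   log2(1.5))
#' @return list: `matches` (gene_id, transcript_log2fc, protein_log2fc,
#'   similar), `transcript_only`, `protein_only`
#' @export
match_transcript_protein <- function(de_records, protein_fc, id_map = NULL,
                                     timepoint = 24,
                                     similar_log2_max = log2(1.5)) {
  de <- de_records[de_records$timepoint == timepoint, , drop = FALSE]
  if (nrow(de) == 0) stop("match_transcript_protein: no DE records at t=", timepoint)
  gene <- de$feature_id
  if (!is.null(id_map)) {
    gene <- id_map$gene_id[match(de$feature_id, id_map$feature_id)]
  }
  de$gene_id <- gene
  de <- de[!is.na(de$gene_id), , drop = FALSE]
  if (anyDuplicated(de$gene_id)) {
    message(sprintf("match_transcript_protein: %d duplicate transcript locus tags; first kept",
                    sum(duplicated(de$gene_id))))
    de <- de[!duplicated(de$gene_id), , drop = FALSE]
  }
  pf <- protein_fc
  if (anyDuplicated(pf$protein_id)) {
    message(sprintf("match_transcript_protein: %d duplicate protein ids; first kept",
                    sum(duplicated(pf$protein_id))))
    pf <- pf[!duplicated(pf$protein_id), , drop = FALSE]
  }
  shared <- intersect(de$gene_id, pf$protein_id)
  t_lfc <- de$log2fc[match(shared, de$gene_id)]
  p_lfc <- log2(pf$fc_combined[match(shared, pf$protein_id)])
  matches <- data.frame(
    gene_id = shared,
    transcript_log2fc = t_lfc,
    protein_log2fc = p_lfc,
    similar = !is.na(t_lfc) & !is.na(p_lfc) &
      abs(t_lfc - p_lfc) < similar_log2_max,
    stringsAsFactors = FALSE
  )
  list(matches = matches,
       transcript_only = setdiff(de$gene_id, pf$protein_id),
       protein_only = setdiff(pf$protein_id, de$gene_id))
}

#' Transcriptome-proteome Pearson correlation
#'
#' @param matches data.frame from [match_transcript_protein()]
#' @return Pearson r over the matched (transcript, protein) log2 fold
#'   changes; NA when either axis has zero variance
#' @export
cross_omics_correlation <- function(matches) {
  ok <- !is.na(matches$transcript_log2fc) & !is.na(matches$protein_log2fc)
  x <- matches$transcript_log2fc[ok]
  y <- matches$protein_log2fc[ok]
  if (length(x) < 3) stop("cross_omics_correlation: need >= 3 complete matches")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Multi-dataset consensus filter for robustly salt-induced genes
#'
#' A gene passes when its log2 fold change strictly exceeds `t_thresh`
#' (1.5-fold) in all three transcriptome datasets and strictly exceeds
#' `p_thresh` (1.3-fold) in the proteome dataset. The gene universe is the
#' intersection of genes present in all four tables; genes absent from any
#' table are reported separately since they can never pass. Passing genes
#' are additionally partitioned by whether their protein was identified
#' (non-missing proteome value before intersection).
#'
#' @param transcriptomes list of 3 data.frames (gene_id, log2fc)
#' @param proteome data.frame (gene_id, log2fc)
#' @param t_thresh transcriptome threshold, strict > (default 0.58)
#' @param p_thresh proteome threshold, strict > (default 0.38)
#' @return list: `records` (gene_id, t1..t3, p, passes), `passing`
#'   (character vector), `not_in_all` (genes missing from >= 1 table)
#' @export
consensus_filter <- function(transcriptomes, proteome, t_thresh = 0.58,
                             p_thresh = 0.38) {
  if (length(transcriptomes) != 3) {
    stop("consensus_filter: exactly 3 transcriptome tables required")
  }
  tables <- c(transcriptomes, list(proteome))
  for (tb in tables) {
    if (!all(c("gene_id", "log2fc") %in% names(tb))) {
      stop("consensus_filter: each table needs gene_id and log2fc columns")
    }
  }
  all_genes <- unique(unlist(lapply(tables, `[[`, "gene_id")))
  universe <- Reduce(intersect, lapply(tables, `[[`, "gene_id"))
  vals <- vapply(tables, function(tb) tb$log2fc[match(universe, tb$gene_id)],
                 numeric(length(universe)))
  vals <- matrix(vals, nrow = length(universe))
  passes <- !apply(vals, 1, anyNA) &
    vals[, 1] > t_thresh & vals[, 2] > t_thresh & vals[, 3] > t_thresh &
    vals[, 4] > p_thresh
  records <- data.frame(
    gene_id = universe,
    t1_log2fc = vals[, 1], t2_log2fc = vals[, 2], t3_log2fc = vals[, 3],
    protein_log2fc = vals[, 4],
    passes = passes,
    stringsAsFactors = FALSE
  )
  list(records = records,
       passing = universe[passes],
       not_in_all = setdiff(all_genes, universe))
}

#' KO-term enrichment per expression cluster
#'
#' One-sided hypergeometric test for over-representation of each KO term in
#' each cluster: with N genes in the universe, K of them carrying the term,
#' and a cluster of size n containing k term members, the upper-tail
#' probability of drawing at least k term members in n draws without
#' replacement. Benjamini-Hochberg adjustment is applied across terms
#' within each cluster. Terms absent from a cluster (k = 0) are skipped;
#' empty clusters are skipped with a warning. Genes may carry several terms.
#'
#' @param assignments data.frame (feature_id, cluster), NA cluster ignored
#' @param ko_annotation data.frame (gene_id, ko_term), one row per
#'   gene-term link; gene ids must refer to universe members
#' @param universe character vector of genes the draw is from (default: all
#'   assigned features)
#' @return data.frame: cluster, ko_term, k, n, K, N, p_value, p_adjusted,
#'   ordered by cluster then p_value
#' @export
ko_enrichment <- function(assignments, ko_annotation, universe = NULL) {
  asn <- assignments[!is.na(assignments$cluster), , drop = FALSE]
  if (is.null(universe)) universe <- unique(asn$feature_id)
  asn <- asn[asn$feature_id %in% universe, , drop = FALSE]
  ko <- ko_annotation[ko_annotation$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  term_sizes <- table(ko$ko_term)
  out <- list()
  for (cl in sort(unique(asn$cluster))) {
    members <- asn$feature_id[asn$cluster == cl]
    n <- length(members)
    if (n == 0) {
      warning("ko_enrichment: empty cluster ", cl, " skipped", call. = FALSE)
      next
    }
    in_cl <- ko[ko$gene_id %in% members, , drop = FALSE]
    if (nrow(in_cl) == 0) next
    ks <- table(in_cl$ko_term)
    terms <- names(ks)
    K <- as.integer(term_sizes[terms])
    k <- as.integer(ks)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    out[[length(out) + 1]] <- data.frame(
      cluster = cl, ko_term = terms, k = k, n = n, K = K, N = N,
      p_value = p, p_adjusted = stats::p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(cluster = integer(), ko_term = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p_value = numeric(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$cluster, res$p_value, res$ko_term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
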