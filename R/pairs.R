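#' Find opposite-strand overlapping asRNA:mRNA pairs
#'
#' Every (asRNA, mRNA) duo on the same replicon whose intervals overlap by
#' at least 1 bp on opposite strands is a candidate pair; an asRNA
#' overlapping several mRNAs yields one pair per mRNA. Overlap is computed
#' on the half-open intervals, so features that merely touch end-to-start do
#' not pair. Features without strand information cannot pair and are
#' skipped. An asRNA overlapping only the 3' end of a gene still pairs.
#'
#' @param features feature_set
#' @return data.frame: asrna_id, mrna_id, overlap_bp
#' @export
find_antisense_pairs <- function(features) {
  stopifnot(inherits(features, "feature_set"))
  stranded <- features[features$strand %in% c("+", "-"), , drop = FALSE]
  as_f <- stranded[stranded$feature_type == "asRNA", , drop = FALSE]
  m_f <- stranded[stranded$feature_type == "mRNA", , drop = FALSE]
  empty <- data.frame(asrna_id = character(), mrna_id = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(as_f) == 0 || nrow(m_f) == 0) return(empty)
  gr_as <- GenomicRanges::GRanges(as_f$replicon,
                                  IRanges::IRanges(as_f$start + 1L, as_f$end),
                                  strand = as_f$strand)
  gr_m <- GenomicRanges::GRanges(m_f$replicon,
                                 IRanges::IRanges(m_f$start + 1L, m_f$end),
                                 strand = m_f$strand)
  # opposite strand = same-strand overlap against the strand-inverted mRNAs
  hits <- GenomicRanges::findOverlaps(gr_as, GenomicRanges::invertStrand(gr_m),
                                      minoverlap = 1L, ignore.strand = FALSE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::ranges(gr_as[qi]), GenomicRanges::ranges(gr_m[si])))
  out <- data.frame(asrna_id = as_f$feature_id[qi],
                    mrna_id = m_f$feature_id[si],
                    overlap_bp = as.integer(ov),
                    stringsAsFactors = FALSE)
  out[order(out$asrna_id, out$mrna_id), , drop = FALSE]
}

#' Pearson correlation of two expression profiles
#'
#' Computed over the per-replicate post-shock fold changes (by default 2
#' replicates x 3 time points = 6 values per transcript, matching the
#' individual-measurement heatmaps the classification is based on).
#' Returns `NA` when either profile has zero variance or any missing value.
#'
#' @param asrna_profile,mrna_profile numeric vectors of equal length >= 3
#' @return Pearson r in [-1, 1], or NA
#' @export
pair_correlation <- function(asrna_profile, mrna_profile) {
  if (length(asrna_profile) != length(mrna_profile)) {
    stop("pair_correlation: profile length mismatch")
  }
  if (length(asrna_profile) < 3) stop("pair_correlation: need >= 3 points")
  if (anyNA(asrna_profile) || anyNA(mrna_profile)) return(NA_real_)
  if (stats::sd(asrna_profile) == 0 || stats::sd(mrna_profile) == 0) return(NA_real_)
  stats::cor(asrna_profile, mrna_profile)
}

#' Classify asRNA:mRNA pairs into the four regulation quadrants
#'
#' A pair is eligible when both members carry a cluster assignment and each
#' shows significant differential expression (status != unchanged) at at
#' least one time point. Eligible pairs with |r| >= `r_min` fall into one of
#' four categories determined by the direction labels of the two members'
#' clusters, provided the sign of r is consistent with those directions:
#' opposite directions require r <= -r_min (`as_up_m_down` when the asRNA's
#' cluster is induced, `as_down_m_up` otherwise); same direction requires
#' r >= r_min (`both_up` for induced, `both_down` for repressed). All other
#' pairs are `unclassified`. Pairs whose members lack expression data are
#' dropped with a message.
#'
#' @param pairs data.frame from [find_antisense_pairs()]
#' @param per_replicate_fc per-replicate log2fc expression_table
#' @param assignments data.frame from [assignment_table()] (feature_id,
#'   cluster, direction)
#' @param de_records data.frame from [call_differential()]
#' @param r_min absolute correlation threshold, inclusive (default 0.65)
#' @return data.frame of pair records: asrna_id, mrna_id, overlap_bp, r,
#'   asrna_cluster, mrna_cluster, category, eligible; the per-category
#'   counts are attached as attribute `summary`
#' @export
classify_pairs <- function(pairs, per_replicate_fc, assignments, de_records,
                           r_min = 0.65) {
  stopifnot(inherits(per_replicate_fc, "expression_table"))
  fcv <- per_replicate_fc$values
  have_expr <- pairs$asrna_id %in% rownames(fcv) & pairs$mrna_id %in% rownames(fcv)
  if (any(!have_expr)) {
    message(sprintf("classify_pairs: %d pairs dropped (member missing from expression data)",
                    sum(!have_expr)))
    pairs <- pairs[have_expr, , drop = FALSE]
  }
  cl <- stats::setNames(assignments$cluster, assignments$feature_id)
  dir <- stats::setNames(assignments$direction, assignments$feature_id)
  de_any <- tapply(de_records$status != "unchanged", de_records$feature_id, any)

  n <- nrow(pairs)
  r <- numeric(n)
  as_cl <- cl[pairs$asrna_id]
  m_cl <- cl[pairs$mrna_id]
  category <- character(n)
  eligible <- logical(n)
  for (i in seq_len(n)) {
    r[i] <- pair_correlation(fcv[pairs$asrna_id[i], ], fcv[pairs$mrna_id[i], ])
    a <- pairs$asrna_id[i]; g <- pairs$mrna_id[i]
    eligible[i] <- !is.na(as_cl[i]) && !is.na(m_cl[i]) &&
      isTRUE(de_any[a]) && isTRUE(de_any[g])
    category[i] <- "unclassified"
    if (eligible[i] && !is.na(r[i]) && abs(r[i]) >= r_min) {
      da <- dir[a]; dm <- dir[g]
      if (da == "induced" && dm == "repressed" && r[i] <= -r_min) {
        category[i] <- "as_up_m_down"
      } else if (da == "repressed" && dm == "induced" && r[i] <= -r_min) {
        category[i] <- "as_down_m_up"
      } else if (da == "induced" && dm == "induced" && r[i] >= r_min) {
        category[i] <- "both_up"
      } else if (da == "repressed" && dm == "repressed" && r[i] >= r_min) {
        category[i] <- "both_down"
      }
    }
  }
  out <- data.frame(
    asrna_id = pairs$asrna_id, mrna_id = pairs$mrna_id,
    overlap_bp = pairs$overlap_bp, r = r,
    asrna_cluster = unname(as_cl), mrna_cluster = unname(m_cl),
    category = category, eligible = eligible,
    stringsAsFactors = FALSE
  )
  cats <- c("as_up_m_down", "as_down_m_up", "both_up", "both_down", "unclassified")
  attr(out, "summary") <- data.frame(
    category = cats,
    n = vapply(cats, function(cc) sum(out$category == cc), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}
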