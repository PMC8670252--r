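#' Average probe-level signals into feature-level signals
#'
#' Microarray features are covered by several independent probes; the
#' feature-level signal in each sample is the arithmetic mean of its probes'
#' values, ignoring missing values. A feature is dropped (and counted in a
#' message) when all of its probes are missing in at least one column.
#' Probes without a mapping are dropped with a count logged. Aggregating an
#' already feature-level table under the identity map changes nothing.
#'
#' @param probe_table expression_table of probe-level log2 signals
#' @param probe_map data.frame with columns `probe_id`, `feature_id`
#' @return expression_table of feature-level log2 signals
#' @export
aggregate_probes <- function(probe_table, probe_map) {
  stopifnot(inherits(probe_table, "expression_table"))
  if (probe_table$value_kind != "signal") {
    stop("aggregate_probes: input must be a signal table")
  }
  if (!all(c("probe_id", "feature_id") %in% names(probe_map))) {
    stop("aggregate_probes: probe_map needs probe_id and feature_id columns")
  }
  probes <- rownames(probe_table$values)
  map <- probe_map[probe_map$probe_id %in% probes, , drop = FALSE]
  n_unmapped <- sum(!probes %in% probe_map$probe_id)
  if (nrow(map) == 0) stop("aggregate_probes: no probe ids in common with the table")
  if (n_unmapped > 0) {
    message(sprintf("aggregate_probes: %d unmapped probes dropped", n_unmapped))
  }
  vals <- probe_table$values[map$probe_id, , drop = FALSE]
  grp <- factor(map$feature_id, levels = unique(map$feature_id))
  agg <- apply(vals, 2, function(col) {
    tapply(col, grp, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  })
  agg <- matrix(agg, nrow = nlevels(grp),
                dimnames = list(levels(grp), colnames(vals)))
  incomplete <- apply(agg, 1, anyNA)
  if (any(incomplete)) {
    message(sprintf("aggregate_probes: %d features dropped (all probes missing in some column)",
                    sum(incomplete)))
    agg <- agg[!incomplete, , drop = FALSE]
  }
  expression_table(agg, probe_table$design, "signal")
}

#' Compute log2 fold changes versus the reference time point
#'
#' Two tables are derived from replicate log2 signals: (a) the replicate-mean
#' log2 fold change per feature and post-shock time point,
#' `mean(treated replicates) - mean(reference replicates)`; (b) the
#' per-replicate log2 fold change (each treated replicate versus the
#' reference replicate mean), retained for correlation analyses where
#' replicate means would leave too few points. Features whose reference is
#' entirely missing get missing fold changes.
#'
#' @param table expression_table of log2 signals
#' @param design experiment_design (defaults to the table's own)
#' @return list with elements `mean_fc` (columns `t<hours>`) and
#'   `per_replicate_fc` (columns `t<hours>_r<rep>`), both value_kind "log2fc"
#' @export
compute_fold_changes <- function(table, design = table$design) {
  stopifnot(inherits(table, "expression_table"))
  if (table$value_kind != "signal") stop("compute_fold_changes: need a signal table")
  if (is.null(design)) stop("compute_fold_changes: no design available")
  tps <- design$timepoints
  ref <- tps[1]
  reps <- seq_len(design$replicates)
  col_of <- function(tp, r) sprintf("t%s_r%d", fmt_tp(tp), r)
  ref_cols <- vapply(reps, function(r) col_of(ref, r), character(1))
  ref_mean <- rowMeans(table$values[, ref_cols, drop = FALSE], na.rm = TRUE)
  ref_mean[apply(table$values[, ref_cols, drop = FALSE], 1, function(v) all(is.na(v)))] <- NA_real_

  post <- tps[-1]
  mean_fc <- matrix(NA_real_, nrow(table$values), length(post),
                    dimnames = list(rownames(table$values),
                                    sprintf("t%s", fmt_tp(post))))
  rep_fc <- matrix(NA_real_, nrow(table$values), length(post) * length(reps),
                   dimnames = list(rownames(table$values),
                                   as.vector(t(outer(post, reps, col_of)))))
  for (i in seq_along(post)) {
    cols <- vapply(reps, function(r) col_of(post[i], r), character(1))
    treated <- table$values[, cols, drop = FALSE]
    tmean <- rowMeans(treated, na.rm = TRUE)
    tmean[apply(treated, 1, function(v) all(is.na(v)))] <- NA_real_
    mean_fc[, i] <- tmean - ref_mean
    for (r in reps) {
      rep_fc[, col_of(post[i], r)] <- treated[, r] - ref_mean
    }
  }
  list(
    mean_fc = expression_table(mean_fc, design = NULL, value_kind = "log2fc"),
    per_replicate_fc = expression_table(rep_fc, design = NULL, value_kind = "log2fc")
  )
}

#' Call differentially expressed features per time point
#'
#' For each feature and post-shock time point, a two-sided two-sample test
#' on the per-replicate log2 signals (treated versus reference) gives the
#' raw p-value; Benjamini-Hochberg adjustment across features within a time
#' point is reported alongside. Status follows the classic cut-off pair: up
#' when log2fc >= `lfc_min` and raw p < `alpha`; down when log2fc <=
#' `-lfc_min` and raw p < `alpha`; otherwise unchanged. Zero-variance /
#' tied groups get p = 1 (conservative; avoids NaN propagation); groups with
#' fewer than two complete replicates get a missing p and unchanged status.
#'
#' With `test = "pooled"` (the default) the p-value comes from a
#' pooled-variance t-test, equivalent to a two-group one-way ANOVA and thus
#' the same treatment the protein abundances receive. With
#' `test = "welch"` the Welch unequal-variance t-test is used instead.
#' With duplicate hybridizations (n = 2 per group) Welch's Satterthwaite
#' degrees of freedom can collapse towards 1 and the test loses most of its
#' power, which is why the pooled test is the default for this design.
#'
#' @param fc_table replicate-mean log2fc expression_table from
#'   [compute_fold_changes()]
#' @param signal_table the underlying signal expression_table
#' @param design experiment_design
#' @param lfc_min absolute log2 fold-change threshold (default 1)
#' @param alpha raw p-value threshold (default 0.05)
#' @param test "pooled" (pooled-variance t / two-group ANOVA, default) or
#'   "welch"
#' @return data.frame of DE records: feature_id, timepoint, log2fc, p_value,
#'   p_adjusted, status
#' @export
call_differential <- function(fc_table, signal_table, design = signal_table$design,
                              lfc_min = 1, alpha = 0.05,
                              test = c("pooled", "welch")) {
  test <- match.arg(test)
  stopifnot(inherits(fc_table, "expression_table"),
            inherits(signal_table, "expression_table"))
  common <- intersect(rownames(fc_table$values), rownames(signal_table$values))
  if (length(common) == 0) stop("call_differential: tables share no features")
  tps <- design$timepoints
  ref <- tps[1]
  reps <- seq_len(design$replicates)
  col_of <- function(tp, r) sprintf("t%s_r%d", fmt_tp(tp), r)
  ref_cols <- vapply(reps, function(r) col_of(ref, r), character(1))
  warned <- FALSE
  out <- list()
  for (tp in tps[-1]) {
    cols <- vapply(reps, function(r) col_of(tp, r), character(1))
    lfc <- fc_table$values[common, sprintf("t%s", fmt_tp(tp))]
    pv <- vapply(common, function(f) {
      x <- signal_table$values[f, cols]
      y <- signal_table$values[f, ref_cols]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) {
        if (!warned) {
          warning("call_differential: < 2 replicates in a group for some features; p set missing",
                  call. = FALSE)
          warned <<- TRUE
        }
        return(NA_real_)
      }
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        # tie -> conservative p = 1; perfectly separated constants -> p = 0
        return(if (mean(x) == mean(y)) 1 else 0)
      }
      tryCatch(stats::t.test(x, y, var.equal = (test == "pooled"))$p.value,
               error = function(e) 1)
    }, numeric(1))
    padj <- stats::p.adjust(pv, method = "BH")
    status <- rep("unchanged", length(common))
    up <- !is.na(lfc) & !is.na(pv) & lfc >= lfc_min & pv < alpha
    down <- !is.na(lfc) & !is.na(pv) & lfc <= -lfc_min & pv < alpha
    status[up] <- "up"
    status[down] <- "down"
    out[[length(out) + 1]] <- data.frame(
      feature_id = common, timepoint = tp, log2fc = unname(lfc),
      p_value = unname(pv), p_adjusted = unname(padj), status = status,
      stringsAsFactors = FALSE
    )
    message(sprintf("call_differential: t=%s h: %d up, %d down of %d features",
                    format(tp), sum(up), sum(down), length(common)))
  }
  do.call(rbind, out)
}

#' Retain features whose profile moves enough to cluster
#'
#' Keeps exactly the features whose maximum absolute log2 fold change over
#' the post-shock time points is at least `threshold` (inclusive), reducing
#' noise and false positives before soft clustering.
#'
#' @param fc_table replicate-mean log2fc expression_table
#' @param threshold log2 units (default 1)
#' @return expression_table subset
#' @export
prefilter_for_clustering <- function(fc_table, threshold = 1) {
  stopifnot(inherits(fc_table, "expression_table"))
  if (fc_table$value_kind != "log2fc") stop("prefilter_for_clustering: need a log2fc table")
  mx <- apply(abs(fc_table$values), 1, max, na.rm = TRUE)
  mx[!is.finite(mx)] <- -Inf
  keep <- mx >= threshold
  message(sprintf("prefilter_for_clustering: %d of %d features retained",
                  sum(keep), length(keep)))
  expression_table(fc_table$values[keep, , drop = FALSE], NULL, "log2fc")
}
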