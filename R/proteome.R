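#' Hi3 absolute quantification from peptide intensities
#'
#' For one LC-MS run, each protein's signal is the mean of its three most
#' intense peptides (proteins with fewer than three peptides use all they
#' have and are flagged). Absolute amounts follow by scaling to the spiked
#' standard of known amount:
#' amount = signal / standard_signal x standard_fmol. Amounts are therefore
#' invariant to any global intensity rescaling of the run.
#'
#' @param peptides data.frame: protein_id, intensity (one row per peptide
#'   observation in this run)
#' @param standard_protein_id id of the spiked standard protein; it must be
#'   present with at least 3 peptides
#' @param standard_fmol amount of standard on column (default 40 fmol)
#' @return data.frame: protein_id, amount_fmol, n_peptides, flagged
#'   (TRUE when fewer than 3 peptides contributed)
#' @export
hi3_quantify <- function(peptides, standard_protein_id, standard_fmol = 40) {
  if (!all(c("protein_id", "intensity") %in% names(peptides))) {
    stop("hi3_quantify: need protein_id and intensity columns")
  }
  std <- peptides$intensity[peptides$protein_id == standard_protein_id]
  std <- std[!is.na(std)]
  if (length(std) < 3) {
    stop("hi3_quantify: standard protein '", standard_protein_id,
         "' absent or has < 3 peptides")
  }
  top3 <- function(v) {
    v <- sort(v[!is.na(v)], decreasing = TRUE)
    mean(v[seq_len(min(3, length(v)))])
  }
  std_signal <- top3(std)
  ids <- unique(peptides$protein_id)
  sig <- vapply(ids, function(p) top3(peptides$intensity[peptides$protein_id == p]),
                numeric(1))
  npep <- vapply(ids, function(p) sum(!is.na(peptides$intensity[peptides$protein_id == p])),
                 integer(1))
  data.frame(
    protein_id = ids,
    amount_fmol = unname(sig) / std_signal * standard_fmol,
    n_peptides = unname(npep),
    flagged = unname(npep) < 3,
    stringsAsFactors = FALSE
  )
}

#' Filter protein identifications by unique-peptide support
#'
#' Proteins are retained in a fraction only when identified by at least
#' `min_peptides` unique peptides there (boundary inclusive). A named
#' allow-list re-admits specific single-peptide proteins (used in the study
#' for two membrane transporter components known to matter for salt
#' acclimation); re-admitted rows are flagged.
#'
#' @param quants data.frame with at least protein_id, fraction,
#'   n_unique_peptides
#' @param min_peptides minimum unique peptides (default 2)
#' @param allow_list character vector of protein_ids exempt from the rule
#' @return the filtered data.frame with a logical `allow_listed` column
#' @export
filter_identifications <- function(quants, min_peptides = 2, allow_list = character()) {
  if (!"n_unique_peptides" %in% names(quants)) {
    stop("filter_identifications: n_unique_peptides column required")
  }
  keep <- quants$n_unique_peptides >= min_peptides
  allowed <- quants$protein_id %in% allow_list
  out <- quants[keep | allowed, , drop = FALSE]
  out$allow_listed <- (out$protein_id %in% allow_list) &
    out$n_unique_peptides < min_peptides
  rownames(out) <- NULL
  out
}

#' Fraction-weighted fold change
#'
#' Combines the three subcellular fractions into one salt/control ratio by
#' summing protein amounts with the debris fraction down-weighted by
#' `debris_weight` (the debris carries only about a tenth of total
#' protein): S = soluble + membrane + debris/10, and
#' fc_weighted = S_salt / S_control. A fraction missing in a condition
#' contributes 0 to that sum. Because a protein redistributing between
#' soluble and membrane keeps S constant, the weighted ratio stays close to
#' the total-extract ratio even when single-fraction ratios diverge.
#'
#' @param salt,control numeric length-3 vectors of replicate-mean fmol in
#'   order (soluble, membrane, debris); NA = not detected
#' @param debris_weight divisor for the debris amounts (default 10)
#' @return linear fold change, or NA when the control sum is 0 or both sums
#'   are 0/undefined
#' @export
weighted_fraction_fc <- function(salt, control, debris_weight = 10) {
  stopifnot(length(salt) == 3, length(control) == 3)
  w <- c(1, 1, 1 / debris_weight)
  if (all(is.na(salt)) && all(is.na(control))) return(NA_real_)
  s_salt <- sum(salt * w, na.rm = TRUE)
  s_ctrl <- sum(control * w, na.rm = TRUE)
  if (s_ctrl == 0) return(NA_real_)
  s_salt / s_ctrl
}

#' Combine the weighted-fraction and total-extract fold changes
#'
#' The final fold change is the arithmetic mean of the two linear ratios;
#' when only one of the two is available it is used directly. With
#' `scale = "geometric"` the mean is taken on the log scale instead.
#'
#' @param fc_weighted,fc_total linear ratios (NA = unavailable)
#' @param scale "linear" (default) or "geometric"
#' @return combined linear fold change, NA when neither input is defined
#' @export
combined_fold_change <- function(fc_weighted, fc_total, scale = c("linear", "geometric")) {
  scale <- match.arg(scale)
  n <- max(length(fc_weighted), length(fc_total))
  fc_weighted <- rep_len(fc_weighted, n)
  fc_total <- rep_len(fc_total, n)
  both <- !is.na(fc_weighted) & !is.na(fc_total)
  out <- ifelse(is.na(fc_weighted), fc_total, fc_weighted)
  if (scale == "linear") {
    out[both] <- (fc_weighted[both] + fc_total[both]) / 2
  } else {
    out[both] <- sqrt(fc_weighted[both] * fc_total[both])
  }
  out
}

#' Per-protein fold changes from a long quantification table
#'
#' Takes replicate-level amounts (columns protein_id, fraction, condition,
#' replicate, amount_fmol, n_unique_peptides), applies the identification
#' filter, computes replicate means per (protein, fraction, condition), and
#' derives fc_total, fc_weighted and fc_combined per protein.
#'
#' @param quants long-format data.frame (fractions "total", "soluble",
#'   "membrane", "debris"; conditions "control", "salt")
#' @param min_peptides identification filter threshold (default 2)
#' @param allow_list single-peptide proteins to keep regardless
#' @param debris_weight see [weighted_fraction_fc()]
#' @param scale see [combined_fold_change()]
#' @return data.frame: protein_id, fc_total, fc_weighted, fc_combined
#' @export
proteome_fold_changes <- function(quants, min_peptides = 2,
                                  allow_list = character(),
                                  debris_weight = 10,
                                  scale = "linear") {
  quants <- filter_identifications(quants, min_peptides, allow_list)
  means <- stats::aggregate(amount_fmol ~ protein_id + fraction + condition,
                            data = quants, FUN = mean, na.rm = TRUE, na.action = NULL)
  ids <- sort(unique(means$protein_id))
  get_mean <- function(p, fr, cond) {
    v <- means$amount_fmol[means$protein_id == p & means$fraction == fr &
                             means$condition == cond]
    if (length(v) == 0 || is.nan(v)) NA_real_ else v
  }
  fc_total <- fc_weighted <- numeric(length(ids))
  for (i in seq_along(ids)) {
    p <- ids[i]
    tot_s <- get_mean(p, "total", "salt"); tot_c <- get_mean(p, "total", "control")
    fc_total[i] <- if (!is.na(tot_s) && !is.na(tot_c) && tot_c > 0) tot_s / tot_c else NA_real_
    salt <- c(get_mean(p, "soluble", "salt"), get_mean(p, "membrane", "salt"),
              get_mean(p, "debris", "salt"))
    ctrl <- c(get_mean(p, "soluble", "control"), get_mean(p, "membrane", "control"),
              get_mean(p, "debris", "control"))
    fc_weighted[i] <- weighted_fraction_fc(salt, ctrl, debris_weight)
  }
  fc_combined <- combined_fold_change(fc_weighted, fc_total, scale)
  excluded <- is.na(fc_combined)
  if (any(excluded)) {
    message(sprintf("proteome_fold_changes: %d proteins excluded (no defined fold change)",
                    sum(excluded)))
  }
  data.frame(protein_id = ids, fc_total = fc_total, fc_weighted = fc_weighted,
             fc_combined = fc_combined, stringsAsFactors = FALSE)[!excluded, , drop = FALSE]
}

#' Differential protein abundance calls
#'
#' Significance combines a magnitude gate with a one-way ANOVA: a protein is
#' significant when its combined fold change is at least `fc_min` (or at
#' most 1/`fc_min`) and the ANOVA p-value of salt versus control replicate
#' amounts in the chosen fraction is below `alpha`. With two groups the
#' one-way ANOVA is equivalent to a pooled-variance t-test. Amounts are
#' log-transformed before testing by default (variance stabilization for
#' lognormal-like abundance noise). Proteins with fewer than two replicates
#' per condition get a missing p and are never called significant.
#'
#' @param quants long-format replicate amounts (as in
#'   [proteome_fold_changes()])
#' @param fold_changes data.frame from [proteome_fold_changes()]
#' @param fc_min linear fold-change gate (default 1.5)
#' @param alpha p-value gate (default 0.05)
#' @param test_fraction fraction whose replicates feed the test (default
#'   "total")
#' @param log_scale test on log-transformed amounts (default TRUE)
#' @return data.frame: protein_id, fc_total, fc_weighted, fc_combined,
#'   p_value, significant, direction ("up"/"down"/"unchanged")
#' @export
call_differential_proteins <- function(quants, fold_changes, fc_min = 1.5,
                                       alpha = 0.05, test_fraction = "total",
                                       log_scale = TRUE) {
  sub <- quants[quants$fraction == test_fraction, , drop = FALSE]
  pv <- vapply(fold_changes$protein_id, function(p) {
    x <- sub$amount_fmol[sub$protein_id == p & sub$condition == "salt"]
    y <- sub$amount_fmol[sub$protein_id == p & sub$condition == "control"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (log_scale) {
      if (any(c(x, y) <= 0)) return(NA_real_)
      x <- log(x); y <- log(y)
    }
    if (stats::sd(c(x, y)) == 0) return(1)
    vals <- c(x, y)
    grp <- factor(rep(c("salt", "control"), c(length(x), length(y))))
    stats::oneway.test(vals ~ grp, var.equal = TRUE)$p.value
  }, numeric(1))
  fc <- fold_changes$fc_combined
  sig <- !is.na(pv) & pv < alpha & (fc >= fc_min | fc <= 1 / fc_min)
  direction <- ifelse(sig & fc >= fc_min, "up",
                      ifelse(sig & fc <= 1 / fc_min, "down", "unchanged"))
  message(sprintf("call_differential_proteins: %d up, %d down of %d proteins",
                  sum(direction == "up"), sum(direction == "down"), length(fc)))
  data.frame(fold_changes, p_value = unname(pv), significant = sig,
             direction = direction, stringsAsFactors = FALSE)
}
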