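#' Default analysis configuration
#'
#' A flat key/value list of every tunable threshold in the pipeline. Each
#' default is the value used throughout the analysis:
#' \describe{
#'   \item{de_lfc_min}{absolute log2 fold-change cut-off for differential
#'     transcript expression (1).}
#'   \item{de_alpha}{p-value cut-off for differential expression (0.05).}
#'   \item{de_test}{two-sample test for transcripts: "pooled"
#'     (pooled-variance t / two-group ANOVA; robust for duplicate
#'     hybridizations) or "welch".}
#'   \item{cluster_prefilter_lfc}{minimum max-|log2fc| over time points for a
#'     transcript to enter clustering (1).}
#'   \item{membership_min}{minimum fuzzy membership for a hard cluster
#'     assignment (0.5).}
#'   \item{combined_membership_min}{minimum summed membership over the two
#'     same-direction clusters to rescue a low-membership transcript (0.6).}
#'   \item{c_range_min, c_range_max}{candidate cluster counts for elbow
#'     selection (2..12).}
#'   \item{fcm_nstart}{random restarts for fuzzy c-means (10).}
#'   \item{fcm_tol, fcm_max_iter}{convergence tolerance on the membership
#'     change (1e-9) and iteration cap (1000).}
#'   \item{pair_r_min}{absolute Pearson correlation required to classify an
#'     asRNA:mRNA pair (0.65).}
#'   \item{protein_fc_min}{linear fold-change cut-off for differential
#'     protein abundance (1.5).}
#'   \item{protein_alpha}{ANOVA p-value cut-off for proteins (0.05).}
#'   \item{protein_min_peptides}{unique peptides required per protein per
#'     fraction (2).}
#'   \item{debris_weight}{divisor applied to debris-fraction amounts in the
#'     weighted sum (10; the debris fraction carries only ~10\% of total
#'     protein).}
#'   \item{hi3_standard_fmol}{spiked amount of the Hi3 quantification
#'     standard (40 fmol).}
#'   \item{similar_log2_max}{max |transcript log2fc - protein log2fc| for a
#'     matched pair to count as similar (log2(1.5)).}
#'   \item{consensus_t_thresh}{log2 threshold (strict >) each transcriptome
#'     dataset must exceed in the consensus filter (0.58, i.e. 1.5-fold).}
#'   \item{consensus_p_thresh}{log2 threshold (strict >) the proteome dataset
#'     must exceed (0.38, i.e. 1.3-fold).}
#'   \item{combined_fc_scale}{"linear" (arithmetic mean of ratios) or
#'     "geometric" for the combined protein fold change.}
#'   \item{protein_test_fraction}{fraction whose replicate amounts feed the
#'     protein significance test ("total").}
#'   \item{protein_test_log}{test protein amounts on the log scale (TRUE).}
#'   \item{pair_correlation_basis}{"per_replicate" (6 post-shock values) or
#'     "mean" (3 replicate means) profiles for pair correlation.}
#' }
#'
#' @return named list
#' @export
default_config <- function() {
  list(
    de_lfc_min = 1,
    de_alpha = 0.05,
    de_test = "pooled",
    cluster_prefilter_lfc = 1,
    membership_min = 0.5,
    combined_membership_min = 0.6,
    c_range_min = 2L,
    c_range_max = 12L,
    fcm_nstart = 10L,
    fcm_tol = 1e-9,
    fcm_max_iter = 1000L,
    pair_r_min = 0.65,
    protein_fc_min = 1.5,
    protein_alpha = 0.05,
    protein_min_peptides = 2L,
    debris_weight = 10,
    hi3_standard_fmol = 40,
    similar_log2_max = log2(1.5),
    consensus_t_thresh = 0.58,
    consensus_p_thresh = 0.38,
    combined_fc_scale = "linear",
    protein_test_fraction = "total",
    protein_test_log = TRUE,
    pair_correlation_basis = "per_replicate"
  )
}

#' Read a flat YAML configuration, filling unset keys from the defaults
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return named list as [default_config()]
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("read_config: file not found: ", path)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("read_config: unknown keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}
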