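#' Normalize metabolite intensities to the internal standard
#'
#' Every sample carries a known spiked amount of carnitine; dividing each
#' metabolite's raw intensity by the carnitine intensity of the same sample
#' cancels sample-to-sample injection and ionization differences. Samples
#' with a zero or missing standard intensity are invalid and excluded with
#' a warning; metabolites left with no valid sample are dropped with a
#' message.
#'
#' @param measurements data.frame: metabolite_id, condition ("control" /
#'   "salt"), replicate, intensity, standard_intensity
#' @return the data.frame restricted to valid samples with a `normalized`
#'   column added
#' @export
normalize_to_standard <- function(measurements) {
  required <- c("metabolite_id", "condition", "replicate", "intensity",
                "standard_intensity")
  if (!all(required %in% names(measurements))) {
    stop("normalize_to_standard: missing columns: ",
         paste(setdiff(required, names(measurements)), collapse = ", "))
  }
  valid <- !is.na(measurements$standard_intensity) &
    measurements$standard_intensity > 0
  if (any(!valid)) {
    warning(sprintf("normalize_to_standard: %d samples excluded (zero/missing internal standard)",
                    sum(!valid)), call. = FALSE)
  }
  out <- measurements[valid, , drop = FALSE]
  dropped <- setdiff(unique(measurements$metabolite_id), unique(out$metabolite_id))
  if (length(dropped) > 0) {
    message("normalize_to_standard: metabolites dropped (no valid sample): ",
            paste(dropped, collapse = ", "))
  }
  out$normalized <- out$intensity / out$standard_intensity
  rownames(out) <- NULL
  out
}

#' Metabolite fold changes versus the control condition
#'
#' The fold change is the ratio of replicate means of the normalized
#' abundances, salt over control (control thereby reported as exactly 1).
#' Per-condition standard deviations accompany each value.
#'
#' @param normalized data.frame from [normalize_to_standard()]
#' @return data.frame: metabolite_id, fold_change, control_mean (= 1 by
#'   construction of the ratio scale), sd_control, sd_salt, n_control,
#'   n_salt; fold_change is NA when the control mean is 0
#' @export
metabolite_fold_changes <- function(normalized) {
  if (!"normalized" %in% names(normalized)) {
    stop("metabolite_fold_changes: run normalize_to_standard() first")
  }
  ids <- unique(normalized$metabolite_id)
  rows <- lapply(ids, function(id) {
    sub <- normalized[normalized$metabolite_id == id, , drop = FALSE]
    ctrl <- sub$normalized[sub$condition == "control"]
    salt <- sub$normalized[sub$condition == "salt"]
    ctrl <- ctrl[!is.na(ctrl)]; salt <- salt[!is.na(salt)]
    if (length(ctrl) < 1 || length(salt) < 1) {
      stop("metabolite_fold_changes: ", id, " lacks a replicate in one condition")
    }
    cm <- mean(ctrl)
    fc <- if (cm == 0) NA_real_ else mean(salt) / cm
    data.frame(
      metabolite_id = id, fold_change = fc, control_mean = 1,
      sd_control = if (cm == 0 || length(ctrl) < 2) NA_real_ else stats::sd(ctrl / cm),
      sd_salt = if (cm == 0 || length(salt) < 2) NA_real_ else stats::sd(salt / cm),
      n_control = length(ctrl), n_salt = length(salt),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
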