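#' Experiment design for the salt-shock time course
#'
#' The design is a reference time point (0 h, unstressed) followed by
#' post-shock sampling times, each measured in a fixed number of replicate
#' hybridizations. The default mirrors the study layout: 0, 0.5, 2 and 24 h
#' with duplicate hybridizations per sampling point.
#'
#' @param timepoints numeric vector of hours, strictly increasing; the first
#'   entry is the reference.
#' @param replicates replicates per time point (>= 1).
#' @return object of class `experiment_design`
#' @export
experiment_design <- function(timepoints = c(0, 0.5, 2, 24), replicates = 2) {
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 2 || any(diff(timepoints) <= 0)) {
    stop("experiment_design: timepoints must be strictly increasing, length >= 2")
  }
  if (anyDuplicated(timepoints)) stop("experiment_design: duplicate timepoints")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("experiment_design: replicates must be >= 1")
  structure(list(timepoints = timepoints, replicates = replicates),
            class = "experiment_design")
}

#' Column labels for a design: t<hours>_r<replicate>
#' @param design experiment_design
#' @return character vector, time-major order
#' @export
design_columns <- function(design) {
  as.vector(t(outer(design$timepoints, seq_len(design$replicates),
                    function(tp, r) sprintf("t%s_r%d", fmt_tp(tp), r))))
}

# scalar-wise timepoint formatting ("0", "0.5", "24"), never width-padded
fmt_tp <- function(tp) {
  vapply(tp, function(x) format(x, trim = TRUE), character(1))
}

#' Expression table
#'
#' A feature-or-probe by sample matrix of log2 values together with the
#' design it was measured under. `value_kind` distinguishes absolute log2
#' signals from log2 fold changes versus the reference time point. Missing
#' values are explicit `NA`s, never zero.
#'
#' @param values numeric matrix; rownames are feature/probe ids.
#' @param design experiment_design the columns conform to (may be `NULL`
#'   for derived tables whose columns are not (timepoint, replicate) pairs).
#' @param value_kind "signal" or "log2fc".
#' @return object of class `expression_table`
#' @export
expression_table <- function(values, design = NULL, value_kind = c("signal", "log2fc")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression_table: values must have rownames")
  if (anyDuplicated(rownames(values))) stop("expression_table: duplicate row ids")
  if (!is.null(design)) {
    expected <- design_columns(design)
    if (!identical(colnames(values), expected)) {
      stop("expression_table: column labels do not match the design; expected ",
           paste(expected, collapse = ", "))
    }
  }
  structure(list(values = values, design = design, value_kind = value_kind),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table [%s]: %d features x %d columns\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_table <- function(x) dim(x$values)

#' Read a tab-separated expression table
#'
#' The first column holds feature/probe ids; remaining column headers must be
#' `t<hours>_r<replicate>` labels matching `design`. Blank cells and "NA"
#' become explicit missing values.
#'
#' @param path TSV file
#' @param design experiment_design
#' @param value_kind "signal" (default) or "log2fc"
#' @return expression_table
#' @export
read_expression <- function(path, design, value_kind = "signal") {
  if (!file.exists(path)) stop("read_expression: file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (ncol(df) < 2) stop("read_expression: need an id column plus data columns")
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  expected <- design_columns(design)
  if (!identical(colnames(body), expected)) {
    stop("read_expression: design mismatch: file columns (",
         paste(colnames(body), collapse = ", "), ") != design columns (",
         paste(expected, collapse = ", "), ")")
  }
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      if (length(bad) > 0) {
        stop(sprintf("read_expression: non-numeric cell at row %d, column '%s'",
                     bad[1], colnames(body)[j]))
      }
      body[[j]] <- as.numeric(col)
    }
  }
  values <- as.matrix(body)
  rownames(values) <- ids
  expression_table(values, design, value_kind)
}

#' Write an expression table (or any rectangular result) as TSV
#'
#' Columns are written in a deterministic order with floats rendered at 6
#' significant digits, so stage outputs re-read into the same records at the
#' declared precision.
#'
#' @param x expression_table or data.frame
#' @param path output TSV
#' @param digits significant digits for numeric columns
#' @export
write_table <- function(x, path, digits = 6) {
  if (inherits(x, "expression_table")) {
    df <- data.frame(feature_id = rownames(x$values), x$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    df <- x
  } else if (is.list(x) && length(x) > 0 && all(vapply(x, is.list, logical(1)))) {
    schemas <- unique(lapply(x, names))
    if (length(schemas) != 1) stop("write_table: records have heterogeneous schemas")
    df <- do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    stop("write_table: unsupported input")
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(df[[j]]), NA, signif(df[[j]], digits))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plain TSV written by [write_table()]
#' @param path TSV file
#' @return data.frame
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("read_table: file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"))
}
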