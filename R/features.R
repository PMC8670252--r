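#' Genomic feature annotation
#'
#' A `feature_set` is the package's annotation container: one row per
#' transcript-level feature (mRNA, antisense RNA, trans-encoded sRNA, 5'UTR
#' or internal-TSS transcript), with strand and coordinates on a replicon.
#' Coordinates are stored 0-based, half-open (`[start, end)`); conversion
#' from the 1-based inclusive GFF3 convention happens only at the I/O
#' boundary, so all interval arithmetic inside the package uses a single
#' convention.
#'
#' @param features data.frame with columns `feature_id`, `feature_type`
#'   (one of `r paste(sprintf('"%s"', FEATURE_TYPES), collapse = ", ")`),
#'   `replicon`, `start` (0-based, inclusive), `end` (exclusive), `strand`
#'   (`"+"`, `"-"`, or `"."`), and optionally `gene_id` (locus tag of the
#'   host or cognate gene; `NA` where not applicable).
#' @return An object of class `feature_set` (a validated data.frame).
#' @export
feature_set <- function(features) {
  required <- c("feature_id", "feature_type", "replicon", "start", "end", "strand")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("feature_set: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"gene_id" %in% names(features)) features$gene_id <- NA_character_
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  features$feature_id <- as.character(features$feature_id)
  features$feature_type <- as.character(features$feature_type)
  features$strand <- as.character(features$strand)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyDuplicated(features$feature_id)) {
    stop("feature_set: duplicate feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]), collapse = ", "))
  }
  bad_type <- setdiff(unique(features$feature_type), FEATURE_TYPES)
  if (length(bad_type) > 0) {
    stop("feature_set: unknown feature_type: ", paste(bad_type, collapse = ", "))
  }
  if (nrow(features) > 0 && any(features$start >= features$end)) {
    bad <- features$feature_id[features$start >= features$end]
    stop("feature_set: start >= end for: ", paste(bad, collapse = ", "))
  }
  if (!all(features$strand %in% c("+", "-", "."))) {
    stop("feature_set: strand must be '+', '-' or '.'")
  }
  rownames(features) <- NULL
  class(features) <- c("feature_set", "data.frame")
  features
}

#' Recognized feature types
#' @export
FEATURE_TYPES <- c("mRNA", "asRNA", "sRNA", "utr5", "internal")

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set with %d features on %d replicon(s)\n",
              nrow(x), length(unique(x$replicon))))
  print(table(x$feature_type))
  invisible(x)
}

#' Convert a feature_set to GRanges (1-based, closed intervals)
#'
#' Features with strand `"."` get GRanges strand `"*"`.
#'
#' @param fs feature_set
#' @return GRanges with metadata columns `feature_id`, `feature_type`, `gene_id`.
#' @export
as_granges <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  strand <- ifelse(fs$strand == ".", "*", fs$strand)
  GenomicRanges::GRanges(
    seqnames = fs$replicon,
    ranges = IRanges::IRanges(start = fs$start + 1L, end = fs$end),
    strand = strand,
    feature_id = fs$feature_id,
    feature_type = fs$feature_type,
    gene_id = fs$gene_id
  )
}

#' Read a GFF3 annotation into a feature_set
#'
#' The feature type is taken from the GFF3 `type` column when it matches one
#' of the recognized types, otherwise from a `feature_type` attribute.
#' Unrecognized types are rejected unless `default_type` supplies a fallback.
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @param default_type optional fallback type for unrecognized entries;
#'   `NULL` (default) rejects them.
#' @return feature_set
#' @export
read_annotation <- function(path, default_type = NULL) {
  if (!file.exists(path)) stop("read_annotation: file not found: ", path)
  n_lines <- length(readLines(path, warn = FALSE))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("read_annotation: GFF3 parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0) {
    warning("read_annotation: no features in ", path)
    return(feature_set(data.frame(
      feature_id = character(), feature_type = character(),
      replicon = character(), start = integer(), end = integer(),
      strand = character(), gene_id = character(),
      stringsAsFactors = FALSE
    )))
  }
  md <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(gr$type)
  if ("feature_type" %in% names(md)) {
    attr_type <- as.character(md$feature_type)
    type <- ifelse(type %in% FEATURE_TYPES, type,
                   ifelse(!is.na(attr_type), attr_type, type))
  }
  unknown <- !(type %in% FEATURE_TYPES)
  if (any(unknown)) {
    if (is.null(default_type)) {
      stop("read_annotation: unrecognized feature type(s): ",
           paste(unique(type[unknown]), collapse = ", "),
           " (set default_type to map them)")
    }
    type[unknown] <- default_type
  }
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  if (anyNA(id)) stop("read_annotation: every feature needs an ID attribute")
  gene_id <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else NA_character_
  fs <- data.frame(
    feature_id = id,
    feature_type = type,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # GFF3 1-based -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gene_id,
    stringsAsFactors = FALSE
  )
  fs$strand[fs$strand == "*"] <- "."
  n_lines  # touched so malformed early lines surface via readLines above
  feature_set(fs)
}

#' Write a feature_set as GFF3
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive GFF3 coordinates. Round-tripping a
#' feature_set through GFF3 reproduces start/end exactly.
#'
#' @param fs feature_set
#' @param path output file
#' @export
write_annotation <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  lines <- c("##gff-version 3")
  if (nrow(fs) > 0) {
    attr_col <- sprintf("ID=%s%s", fs$feature_id,
                        ifelse(is.na(fs$gene_id), "", sprintf(";gene_id=%s", fs$gene_id)))
    lines <- c(lines, sprintf(
      "%s\tsaltomics\t%s\t%d\t%d\t.\t%s\t.\t%s",
      fs$replicon, fs$feature_type, fs$start + 1L, fs$end, fs$strand, attr_col
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Strand-aware overlap query against a feature_set
#'
#' Returns the features whose `[start, end)` interval intersects the query
#' interval on the given replicon and strand.
#'
#' @param fs feature_set
#' @param replicon replicon name
#' @param start,end query interval, 0-based half-open
#' @param strand query strand ("+" or "-")
#' @return feature_set subset
#' @export
query_overlaps <- function(fs, replicon, start, end, strand) {
  stopifnot(start < end, strand %in% c("+", "-"))
  hit <- fs$replicon == replicon & fs$strand == strand &
    fs$start < end & fs$end > start
  out <- fs[hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_set", "data.frame")
  out
}
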