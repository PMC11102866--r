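# Tabular readers/writers: count tables, fragment tables, trace tables.
# All coordinates are 0-based half-open internally; conversion to 1-based
# closed happens only at display/CLI boundaries.

.require_cols <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " table '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
}

#' Read a SeEN-seq count table
#'
#' Expects a TSV with columns `construct_id`, `replicate`, `fraction`
#' (`bound`/`unbound`) and `count`. Keys must be unique and counts
#' non-negative integers.
#'
#' @param path Path to a tab-separated file with a header.
#' @return A validated data.frame (a `CountTable`).
#' @export
read_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_cols(df, c("construct_id", "replicate", "fraction", "count"),
                "count", path)
  validate_counts(df, path = path)
}

#' Validate a count table
#'
#' @param df data.frame with count-table columns.
#' @param path Label used in error messages.
#' @return `df`, with `replicate` and `count` coerced to integer.
#' @export
validate_counts <- function(df, path = "<counts>") {
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$replicate) || any(df$replicate < 1L))
    stop("count table '", path, "': replicate must be an integer >= 1")
  if (!all(df$fraction %in% c("bound", "unbound")))
    stop("count table '", path, "': fraction must be 'bound' or 'unbound'")
  cnt <- suppressWarnings(as.numeric(df$count))
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("count table '", path, "': count must be an integer >= 0")
  df$count <- as.integer(cnt)
  key <- paste(df$construct_id, df$replicate, df$fraction)
  if (anyDuplicated(key))
    stop("count table '", path, "': duplicate (construct_id, replicate, fraction) key: ",
         key[anyDuplicated(key)])
  df
}

#' Write a count table
#' @param df Count table data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read MNase fragment records
#'
#' Expects a TSV with columns `ref_id`, `start`, `end` and optionally
#' `condition` (`minus_factor`/`plus_factor`). Intervals are 0-based
#' half-open, so fragment length is `end - start`.
#'
#' @param path Path to a tab-separated file with a header.
#' @param ref_length Optional reference length; if given, `end <= ref_length`
#'   is enforced.
#' @return A validated data.frame of fragment records.
#' @export
read_fragments <- function(path, ref_length = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .require_cols(df, c("ref_id", "start", "end"), "fragment", path)
  validate_fragments(df, ref_length = ref_length, path = path)
}

#' Validate fragment records
#' @inheritParams read_fragments
#' @param df data.frame with fragment columns.
#' @param path Label used in error messages.
#' @return `df` with integer coordinates.
#' @export
validate_fragments <- function(df, ref_length = NULL, path = "<fragments>") {
  df$start <- as.integer(df$start)
  df$end   <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end))
    stop("fragment table '", path, "': non-integer start/end")
  bad <- df$start < 0L | df$start >= df$end
  if (any(bad))
    stop("fragment table '", path, "': need 0 <= start < end (row ",
         which(bad)[1], ")")
  if (!is.null(ref_length) && any(df$end > ref_length))
    stop("fragment table '", path, "': end exceeds reference length ",
         ref_length, " (row ", which(df$end > ref_length)[1], ")")
  if (!is.null(df$condition) &&
      !all(df$condition %in% c("minus_factor", "plus_factor")))
    stop("fragment table '", path,
         "': condition must be 'minus_factor' or 'plus_factor'")
  df
}

#' Write fragment records
#' @param df Fragment data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-molecule fluorescence intensity traces
#'
#' Expects a CSV with columns `molecule_id`, `frame_index`, `time_s`, `donor`
#' and `acceptor`. Frames within a molecule must be strictly increasing in
#' time with a uniform frame interval (tolerance `1e-6` s).
#'
#' @param path Path to a comma-separated file with a header.
#' @return A validated data.frame (a `TraceTable`), ordered by molecule and
#'   frame.
#' @export
read_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("molecule_id", "frame_index", "time_s", "donor", "acceptor"),
                "trace", path)
  validate_traces(df, path = path)
}

#' Validate a trace table
#' @param df data.frame with trace columns.
#' @param path Label used in error messages.
#' @return `df`, ordered by (molecule_id, frame_index).
#' @export
validate_traces <- function(df, path = "<traces>") {
  df$frame_index <- as.integer(df$frame_index)
  if (anyNA(df$frame_index) || any(df$frame_index < 0L))
    stop("trace table '", path, "': frame_index must be an integer >= 0")
  df <- df[order(df$molecule_id, df$frame_index), , drop = FALSE]
  for (id in unique(df$molecule_id)) {
    tm <- df$time_s[df$molecule_id == id]
    if (length(tm) > 1L) {
      dt <- diff(tm)
      if (any(dt <= 0))
        stop("trace table '", path, "': time not strictly increasing for molecule '",
             id, "'")
      if (max(dt) - min(dt) > 1e-6)
        stop("trace table '", path, "': non-uniform frame interval for molecule '",
             id, "' (spread ", format(max(dt) - min(dt)), " s)")
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a trace table
#' @param df Trace data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(df, path) {
  write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
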