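#' Read a DNA FASTA file into sequence records
#'
#' Sequences are uppercased and validated against the strict DNA alphabet
#' `ACGTN`. Any other character (including `U`) is a format error that names
#' the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, one row per record.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("FASTA format error: empty file '", path, "'")
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("FASTA format error: no records in '", path, "'")
  seqs <- toupper(as.character(set))
  ids  <- sub("\\s.*$", "", names(set))
  bad  <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    # locate the first offending line for the error message
    lines <- toupper(readLines(path, warn = FALSE))
    off <- which(!startsWith(lines, ">") & grepl("[^ACGTN[:space:]]", lines))[1]
    stop("FASTA format error: non-DNA character (alphabet ACGTN) in record '",
         ids[bad][1], "' at line ", off, " of '", path, "'")
  }
  if (any(nchar(seqs) == 0L)) {
    stop("FASTA format error: empty sequence for record '",
         ids[nchar(seqs) == 0L][1], "'")
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}
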