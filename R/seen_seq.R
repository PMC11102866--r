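# SeEN-seq: tiled-motif library design on the Widom 601 backbone and
# spike-in normalized enrichment profiles.
#
# Internally motif_start is a 0-based offset on the backbone; construct ids
# encode the 1-based start ("pos1" ... "pos139") so that profile positions
# map directly onto the usual motif-position axis.

#' Tile a motif across a backbone sequence
#'
#' Each construct is the backbone with the motif substituted (never inserted)
#' at one offset.
#'
#' @param backbone A single sequence: a character string, or a one-row
#'   data.frame as returned by [read_fasta()].
#' @param motif Motif sequence (e.g. the 9-bp nuclear-receptor motif
#'   `"TCAAGGCCA"`).
#' @param step Tiling step in bp (default 1).
#' @return data.frame with columns `construct_id` (`pos<N>`, N = 1-based
#'   motif start), `motif_start` (0-based offset) and `sequence`.
#' @examples
#' nrow(tile_motif(strrep("A", 147), "TCAAGGCCA"))  # 139 constructs
#' @export
tile_motif <- function(backbone, motif, step = 1L) {
  if (is.data.frame(backbone)) {
    stopifnot(nrow(backbone) == 1L)
    backbone <- backbone$sequence
  }
  backbone <- toupper(backbone)
  motif <- toupper(motif)
  step <- as.integer(step)
  stopifnot(step >= 1L)
  L <- nchar(backbone)
  m <- nchar(motif)
  if (m > L) stop("motif longer than backbone (", m, " > ", L, ")")
  starts0 <- seq.int(0L, L - m, by = step)
  seqs <- vapply(starts0, function(s) {
    paste0(substr(backbone, 1L, s), motif,
           substr(backbone, s + m + 1L, L))
  }, character(1))
  data.frame(construct_id = paste0("pos", starts0 + 1L),
             motif_start = starts0,
             sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Spike-in normalize a count table
#'
#' Each count is divided by its library size (total counts of its
#' replicate/fraction), then by the library-size-normalized count of the
#' spike-in construct in the same library. The library size cancels
#' algebraically, but both steps are kept for transparency.
#'
#' @param table A count table (see [read_counts()]).
#' @param spike_id Construct id of the spike-in (unmodified backbone).
#' @return The table with columns `library_size` and `normalized` added.
#' @export
normalize_counts <- function(table, spike_id) {
  table <- validate_counts(table)
  table$library_size <- NA_real_
  table$normalized <- NA_real_
  for (rep in unique(table$replicate)) {
    for (frac in c("bound", "unbound")) {
      i <- which(table$replicate == rep & table$fraction == frac)
      if (!length(i)) next
      lib <- sum(table$count[i])
      sp <- i[table$construct_id[i] == spike_id]
      if (!length(sp))
        stop("spike-in construct '", spike_id, "' absent in replicate ", rep,
             ", fraction ", frac)
      if (table$count[sp] == 0L)
        stop("spike-in construct '", spike_id, "' has zero counts in replicate ",
             rep, ", fraction ", frac)
      table$library_size[i] <- lib
      table$normalized[i] <- (table$count[i] / lib) /
        (table$count[sp] / lib)
    }
  }
  table
}

#' Per-construct, per-replicate enrichment scores
#'
#' Enrichment is the log2 fold change of the spike-in normalized bound over
#' unbound fraction. No pseudocounts: a zero count in either fraction makes
#' the score `status = "missing"` (the assay reports such positions as lost,
#' not imputed). The spike-in scores 0 identically.
#'
#' @param table A count table.
#' @param spike_id Spike-in construct id.
#' @return data.frame with columns `construct_id`, `replicate`,
#'   `normalized_bound`, `normalized_unbound`, `enrichment`, `status`.
#' @export
enrichment_scores <- function(table, spike_id) {
  norm <- normalize_counts(table, spike_id)
  b <- norm[norm$fraction == "bound", ]
  u <- norm[norm$fraction == "unbound", ]
  rec <- merge(
    b[, c("construct_id", "replicate", "count", "normalized")],
    u[, c("construct_id", "replicate", "count", "normalized")],
    by = c("construct_id", "replicate"), all = TRUE,
    suffixes = c("_bound", "_unbound"))
  ok <- !is.na(rec$count_bound) & !is.na(rec$count_unbound) &
    rec$count_bound > 0L & rec$count_unbound > 0L
  rec$enrichment <- ifelse(ok,
    log2(rec$normalized_bound / rec$normalized_unbound), NA_real_)
  rec$status <- ifelse(ok, "ok", "missing")
  names(rec)[names(rec) == "normalized_bound"] <- "normalized_bound"
  rec[, c("construct_id", "replicate", "normalized_bound",
          "normalized_unbound", "enrichment", "status")]
}

#' Aggregate enrichment scores into a per-position profile
#'
#' @param records Output of [enrichment_scores()].
#' @param library Optional [tile_motif()] table to attach `motif_start_1based`
#'   by construct id; without it ids of the form `pos<N>` are parsed.
#' @return data.frame with per construct: `motif_start_1based`,
#'   `mean_enrichment`, `sd` (sample s.d., n-1), `n` (replicates with status
#'   ok) and `status` (`ok`, or `missing` when every replicate is missing).
#' @export
enrichment_profile <- function(records, library = NULL) {
  ids <- unique(records$construct_id)
  pos <- if (!is.null(library)) {
    library$motif_start[match(ids, library$construct_id)] + 1L
  } else {
    suppressWarnings(as.integer(sub("^pos", "", ids)))
  }
  rows <- lapply(seq_along(ids), function(i) {
    e <- records$enrichment[records$construct_id == ids[i] &
                              records$status == "ok"]
    n <- length(e)
    data.frame(construct_id = ids[i],
               motif_start_1based = pos[i],
               mean_enrichment = if (n) mean(e) else NA_real_,
               sd = if (n >= 2L) sd(e) else NA_real_,
               n = n,
               status = if (n) "ok" else "missing",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$motif_start_1based), ]
}

#' Assign error-free reads to library constructs by exact sequence match
#'
#' A convenience classifier for synthetic end-to-end tests only; real read
#' assignment (alignment, mapping-quality filtering) is upstream of this
#' package.
#'
#' @param reads Character vector of read sequences (full construct length).
#' @param library A [tile_motif()] table, optionally with a spike-in row
#'   appended.
#' @return Character vector of construct ids (`NA` for no exact match).
#' @export
classify_reads <- function(reads, library) {
  library$construct_id[match(toupper(reads), library$sequence)]
}
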