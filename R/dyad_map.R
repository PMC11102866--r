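# In vitro MNase dyad-density mapping. Fragments are 0-based half-open
# intervals on a reference construct; the midpoint of each nucleosome-sized
# fragment is taken as the dyad. Densities and calls are reported 1-based.

#' Filter fragments by length
#'
#' Keeps fragments whose length (`end - start`) lies in the inclusive range
#' `[min_len, max_len]`. The defaults retain only fully protected
#' nucleosome-core fragments, 145-147 bp.
#'
#' @param fragments Fragment data.frame (see [read_fragments()]).
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The kept subset.
#' @export
filter_fragments <- function(fragments, min_len = 145L, max_len = 147L) {
  stopifnot(min_len <= max_len)
  len <- fragments$end - fragments$start
  fragments[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Per-fragment dyad positions
#'
#' The dyad is the midpoint of the half-open interval, `floor((start + end -
#' 1) / 2)` (0-based): the central base for odd lengths, the lower of the two
#' central bases for even lengths.
#'
#' @param fragments Fragment data.frame.
#' @return Integer vector of 0-based dyad positions.
#' @examples
#' dyad_positions(data.frame(ref_id = "r", start = 0, end = 147))  # 73
#' @export
dyad_positions <- function(fragments) {
  as.integer((fragments$start + fragments$end - 1L) %/% 2L)
}

#' Dyad density profile
#'
#' Density at a position is the percentage of all kept dyads located there;
#' the profile sums to 100.
#'
#' @param dyads Integer vector of 0-based dyad positions.
#' @param ref_length Reference construct length in bp.
#' @param ref_id Reference id recorded on the profile.
#' @param n_total Total fragment count before filtering (bookkeeping;
#'   defaults to `length(dyads)`).
#' @return A `DyadProfile`: list with `ref_id`, `density` (per-bp percentage
#'   vector, index = 1-based bp), `n_fragments_total`, `n_fragments_kept`.
#' @export
dyad_density <- function(dyads, ref_length, ref_id = "ref",
                         n_total = length(dyads)) {
  if (!length(dyads)) stop("no kept fragments: cannot form a dyad density")
  if (any(dyads < 0L | dyads >= ref_length))
    stop("dyad position outside reference [0, ", ref_length, ")")
  density <- 100 * tabulate(dyads + 1L, nbins = ref_length) / length(dyads)
  structure(list(ref_id = ref_id, density = density,
                 n_fragments_total = n_total,
                 n_fragments_kept = length(dyads)),
            class = "DyadProfile")
}

#' @export
print.DyadProfile <- function(x, ...) {
  cat(sprintf("DyadProfile '%s': %d bp, %d/%d fragments kept, peak at bp %d\n",
              x$ref_id, length(x$density), x$n_fragments_kept,
              x$n_fragments_total, which.max(x$density)))
  invisible(x)
}

#' Per-bp log2 fold change of dyad density between conditions
#'
#' @param profile_plus,profile_minus `DyadProfile`s with and without the
#'   factor, on the same reference.
#' @return data.frame with `position_1based`, `log2fc` and `defined`
#'   (positions with zero density in either condition are flagged undefined,
#'   not reported as infinite).
#' @export
density_log2fc <- function(profile_plus, profile_minus) {
  if (profile_plus$ref_id != profile_minus$ref_id ||
      length(profile_plus$density) != length(profile_minus$density))
    stop("profiles are on different references")
  p <- profile_plus$density
  m <- profile_minus$density
  defined <- p > 0 & m > 0
  data.frame(position_1based = seq_along(p),
             log2fc = ifelse(defined, log2(p / m), NA_real_),
             defined = defined)
}

#' Call nucleosome positions from a dyad density profile
#'
#' Greedy peak picking on the window-smoothed density: repeatedly take the
#' global maximum, record the fraction of kept dyads within `window` bp as
#' its weight, suppress `min_separation` bp around it, and stop once the next
#' peak's weight falls below `min_weight`.
#'
#' @param profile A `DyadProfile`.
#' @param window Half-width in bp for smoothing and weight assignment.
#' @param min_separation Minimum distance between calls in bp.
#' @param min_weight Minimum dyad fraction for a call.
#' @return data.frame with `dyad_1based` and `weight`, in descending weight.
#' @export
call_positions <- function(profile, window = 3L, min_separation = 10L,
                           min_weight = 0.05) {
  stopifnot(window >= 1L)
  d <- profile$density
  L <- length(d)
  # centered moving average over +/- window bp
  kern <- rep(1, 2L * window + 1L)
  sm <- as.numeric(stats::filter(c(rep(0, window), d, rep(0, window)),
                                 kern, sides = 2))
  sm <- sm[(window + 1L):(window + L)]
  avail <- rep(TRUE, L)
  calls <- list()
  repeat {
    if (!any(avail)) break
    # ties in the smoothed maximum (e.g. a delta peak under a boxcar) are
    # resolved by the raw density, then by the lowest coordinate
    top <- max(sm[avail])
    cand <- which(avail & sm >= top - 1e-9)
    p <- cand[which.max(d[cand])]
    lo <- max(1L, p - window); hi <- min(L, p + window)
    weight <- sum(d[lo:hi]) / 100
    if (weight < min_weight) break
    calls[[length(calls) + 1L]] <- data.frame(dyad_1based = p, weight = weight)
    supp <- max(1L, p - min_separation):min(L, p + min_separation)
    avail[supp] <- FALSE
  }
  if (!length(calls))
    return(data.frame(dyad_1based = integer(), weight = numeric()))
  out <- do.call(rbind, calls)
  out[order(-out$weight), , drop = FALSE]
}
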