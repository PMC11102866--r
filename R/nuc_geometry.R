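# Nucleosome coordinate arithmetic: signed distances from the dyad and
# superhelical location (SHL) labels. All user-facing positions here are
# 1-based base pairs on the core particle, matching the field's convention
# of quoting motif positions from the 5' end of the top strand.

#' Describe a nucleosome core coordinate frame
#'
#' @param core_length Core particle length in bp (default 147).
#' @param dyad_position 1-based position of the dyad base pair; defaults to
#'   the central base pair of the core, bp 74 for a 147-bp core.
#' @param periodicity Helical periodicity in bp per superhelical turn
#'   (default 10.4, standard for nucleosomal DNA).
#' @return A `NucleosomeFrame` list.
#' @examples
#' nucleosome_frame()                  # 147 bp, dyad 74
#' nucleosome_frame(180, dyad_position = 87)
#' @export
nucleosome_frame <- function(core_length = 147L, dyad_position = NULL,
                             periodicity = 10.4) {
  core_length <- as.integer(core_length)
  stopifnot(core_length >= 1L, periodicity > 0)
  if (is.null(dyad_position)) dyad_position <- (core_length + 1L) %/% 2L
  dyad_position <- as.integer(dyad_position)
  if (dyad_position < 1L || dyad_position > core_length)
    stop("dyad_position must be within [1, core_length]")
  structure(list(core_length = core_length, dyad_position = dyad_position,
                 periodicity = periodicity),
            class = "NucleosomeFrame")
}

#' @export
print.NucleosomeFrame <- function(x, ...) {
  cat(sprintf("NucleosomeFrame: %d bp core, dyad at bp %d, %.1f bp/turn\n",
              x$core_length, x$dyad_position, x$periodicity))
  invisible(x)
}

#' Round to the nearest half-integer, ties away from zero
#'
#' The SHL quantization rule: exact .25/.75 fractions of a turn round away
#' from the dyad, so labels are symmetric under reflection through SHL 0.
#'
#' @param x Numeric vector.
#' @return `x` rounded to multiples of 0.5.
#' @export
round_half <- function(x) {
  sign(x) * floor(2 * abs(x) + 0.5) / 2
}

#' Signed base-pair distance from the dyad
#'
#' Positive values run toward the 3' end of the top strand.
#'
#' @param position 1-based bp position(s) on the core.
#' @param frame A [nucleosome_frame()].
#' @return Integer distance(s) `position - dyad_position`.
#' @examples
#' distance_from_dyad(128, nucleosome_frame())  # 54
#' @export
distance_from_dyad <- function(position, frame = nucleosome_frame()) {
  position <- as.integer(position)
  if (any(position < 1L | position > frame$core_length))
    stop("position outside core [1, ", frame$core_length, "]")
  position - frame$dyad_position
}

#' Superhelical location of a motif
#'
#' The motif is referenced by its central base (start + 4 for a 9-bp motif);
#' the distance of that center from the dyad, in helical turns, is rounded to
#' the nearest half-integer (ties away from zero).
#'
#' @param motif_start 1-based start of the motif on the core.
#' @param motif_length Motif length in bp (default 9).
#' @param frame A [nucleosome_frame()].
#' @return Half-integer SHL label.
#' @examples
#' shl_of_motif(128)   # +5.5
#' @export
shl_of_motif <- function(motif_start, motif_length = 9L,
                         frame = nucleosome_frame()) {
  motif_start <- as.integer(motif_start)
  motif_length <- as.integer(motif_length)
  stopifnot(motif_length >= 1L)
  if (any(motif_start < 1L |
          motif_start + motif_length - 1L > frame$core_length))
    stop("motif not fully inside the core")
  center <- motif_start + (motif_length - 1L) %/% 2L
  round_half(distance_from_dyad(center, frame) / frame$periodicity)
}

#' Relocate an SHL label to a new nucleosome register
#'
#' When the dyad moves on a fixed DNA sequence, a motif keeps its absolute
#' coordinate, so its distance from the dyad shifts by `-(dyad_new -
#' dyad_old)` and the SHL label is re-quantized.
#'
#' @param shl_old Half-integer SHL on the old register.
#' @param dyad_old,dyad_new Old/new dyad positions (bp, same coordinate
#'   system).
#' @param frame A [nucleosome_frame()] supplying the periodicity.
#' @return Half-integer SHL on the new register.
#' @examples
#' relocate_shl(2.5, 87, 108)  # +0.5
#' relocate_shl(2.5, 87, 73)   # +4
#' @export
relocate_shl <- function(shl_old, dyad_old, dyad_new,
                         frame = nucleosome_frame()) {
  if (any(abs(shl_old) > 7))
    stop("|shl_old| > 7 is outside the nucleosome core")
  dist <- shl_old * frame$periodicity
  round_half((dist - (dyad_new - dyad_old)) / frame$periodicity)
}
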