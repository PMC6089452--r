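# CDS-relative coordinates, 1-based with no position 0:
# the first base of the CDS is +1, the last base of the transcript leader
# (TL) is -1. A TL of length L occupies -L .. -1.

#' Convert 1-based index in the concatenated TL+downstream string to a
#' CDS-relative coordinate
#'
#' @param i integer vector of 1-based indices into `paste0(tl, downstream)`.
#' @param tl_length length of the TL in nucleotides.
#' @return integer vector of relative coordinates (negative in the TL,
#'   positive in the CDS; never 0).
#' @keywords internal
rel_coord <- function(i, tl_length) {
  ifelse(i <= tl_length, i - tl_length - 1L, i - tl_length)
}

#' Convert a CDS-relative coordinate to a 1-based index in the
#' concatenated TL+downstream string
#'
#' @param r integer vector of relative coordinates (no zeros).
#' @param tl_length length of the TL in nucleotides.
#' @keywords internal
abs_coord <- function(r, tl_length) {
  stopifnot(all(r != 0L))
  ifelse(r < 0L, r + tl_length + 1L, r + tl_length)
}

#' Reading-frame offset of an upstream AUG relative to the CDS
#'
#' The offset is d mod 3 with d the nucleotide distance from the uAUG first
#' base to the CDS first base; offset 0 means in frame with the CDS.
#'
#' @param start relative coordinate of the uAUG first base (negative).
#' @return integer in 0..2.
#' @keywords internal
frame_offset <- function(start) {
  (-as.integer(start)) %% 3L
}
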