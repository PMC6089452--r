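# shared test helpers: quick record construction and exhaustive sequence
# enumeration at small lengths

rec <- function(tl, down = "ATGGGGTAAGGG", id = "g1") {
  suppressWarnings(tl_record(id, tl, down))
}

enum_seqs <- function(L) {
  bases <- c("A", "C", "G", "T")
  idx <- as.matrix(expand.grid(rep(list(1:4), L)))
  do.call(paste0, as.data.frame(matrix(bases[idx], ncol = L),
                                stringsAsFactors = FALSE))
}

# nucleotide span of an ORF from start to stop third base, accounting for
# the absence of position 0 in the relative coordinate system
rel_span <- function(start, stop3) {
  stop3 - start + 1L - (start < 0L & stop3 > 0L)
}
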