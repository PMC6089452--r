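.STOP_CODONS <- c("TAA", "TAG", "TGA")

.empty_calls <- function() {
  data.frame(gene_id = character(0), start = integer(0),
             stop_third_base = integer(0), length_aa = integer(0),
             frame_offset = integer(0), orf_class = character(0),
             stringsAsFactors = FALSE)
}

# Engine behind scan_transcript(); works on bare strings so that exhaustive
# enumerations and the permutation null avoid record construction overhead.
# Returns a list of parallel vectors (zero-length when there is no call).
.scan_core <- function(tl, downstream, window = 300L) {
  L <- nchar(tl)
  W <- min(nchar(downstream), as.integer(window))
  none <- list(start = integer(0), stop_third_base = integer(0),
               length_aa = integer(0), frame_offset = integer(0),
               orf_class = character(0))
  if (L < 3L) return(none)
  full <- paste0(tl, substr(downstream, 1L, W))
  m <- gregexpr("ATG", substr(full, 1L, L), fixed = TRUE)[[1]]
  if (m[1L] == -1L) return(none)
  n_full <- nchar(full)
  n <- length(m)
  start <- stop3 <- len_aa <- fo <- integer(n)
  cls <- character(n)
  for (k in seq_len(n)) {
    i <- m[k]
    if (i + 3L <= n_full - 2L) {
      js <- seq.int(i + 3L, n_full - 2L, by = 3L)
      hit <- which(substring(full, js, js + 2L) %in% .STOP_CODONS)[1L]
    } else {
      hit <- NA_integer_
    }
    start[k] <- i - L - 1L
    fo[k] <- (L + 1L - i) %% 3L
    if (!is.na(hit)) {
      sa <- js[hit] + 2L
      stop3[k] <- if (sa <= L) sa - L - 1L else sa - L
      len_aa[k] <- hit
    } else {
      stop3[k] <- NA_integer_
      len_aa[k] <- NA_integer_
    }
    cls[k] <- if (!is.na(hit) && stop3[k] <= -1L) {
      "uORF"
    } else if (fo[k] == 0L) {
      "n_terminal_extension"
    } else if (!is.na(hit)) {
      "oORF"
    } else {
      "no_stop_in_window"
    }
  }
  list(start = start, stop_third_base = stop3, length_aa = len_aa,
       frame_offset = fo, orf_class = cls)
}

#' Scan a transcript leader for upstream AUG-initiated ORFs
#'
#' Every AUG lying wholly within the transcript leader (first base at
#' relative position <= -3) opens a candidate ORF, read in codons until the
#' first in-frame stop (TAA/TAG/TGA) within TL + `window` nt of downstream
#' sequence. Calls are classified:
#'
#' * `uORF` - the stop codon lies wholly within the TL (third base <= -1);
#' * `oORF` - the AUG is out of frame with the CDS (frame offset 1 or 2) and
#'   the first in-frame stop ends at or after the CDS first base (third base
#'   >= +1), so the upstream ORF overlaps the CDS start;
#' * `n_terminal_extension` - the AUG is in frame with the CDS (offset 0)
#'   and no stop lies wholly within the TL; translation extends the main
#'   protein rather than encoding an upstream peptide;
#' * `no_stop_in_window` - out-of-frame AUG with no in-frame stop found
#'   within TL + window.
#'
#' Codons containing N match neither AUG nor a stop. Nested and overlapping
#' ORFs are all reported: each upstream AUG is scanned independently, and two
#' AUGs in the same frame may share a stop codon and yield two calls.
#'
#' @param record a [tl_record()].
#' @param window maximum downstream extent (nt past the CDS first base)
#'   searched for an in-frame stop; default 300.
#' @return data.frame with one row per call, ordered by `start`: columns
#'   `gene_id`, `start` (relative coordinate of the uAUG first base),
#'   `stop_third_base` (relative coordinate of the third base of the first
#'   in-frame stop, NA if none found), `length_aa` (sense codons including
#'   the initiator Met, stop excluded), `frame_offset` (0..2), `orf_class`.
#'   Relative coordinates are 1-based with no position 0: CDS first base =
#'   +1, last TL base = -1.
#' @examples
#' r <- tl_record("g1", "ATGTAACC", "ATGGGGTAA")
#' scan_transcript(r)
#' @export
scan_transcript <- function(record, window = 300L) {
  stopifnot(inherits(record, "tl_record"))
  core <- .scan_core(record$tl_seq, record$downstream_seq, window)
  n <- length(core$start)
  if (n == 0L) return(.empty_calls())
  data.frame(gene_id = rep(record$gene_id, n), core,
             stringsAsFactors = FALSE)
}

#' Summarize the ORF calls of one gene
#'
#' Tallies call classes and assigns the gene to a group used by the cohort
#' statistics. N-terminal extensions and open-ended (`no_stop_in_window`)
#' calls never count as uORFs or oORFs.
#'
#' @param calls data.frame of calls from [scan_transcript()], all for one
#'   gene (may be empty).
#' @param tl_length TL length in nt.
#' @param gene_id required when `calls` is empty.
#' @return one-row data.frame: `gene_id`, `tl_length`, counts `n_uORF`,
#'   `n_oORF`, `n_nte`, `n_nostop`, flags `has_uORF`, `has_oORF`, and
#'   `group` in none / uORF_only / oORF_only / both.
#' @export
summarize_gene <- function(calls, tl_length, gene_id = NULL) {
  if (nrow(calls) > 0L) {
    ids <- unique(calls$gene_id)
    if (length(ids) > 1L) {
      stop("calls mix gene_ids: ", paste(ids, collapse = ", "))
    }
    if (is.null(gene_id)) gene_id <- ids
    if (gene_id != ids) stop("gene_id does not match calls")
  } else if (is.null(gene_id)) {
    stop("gene_id required when calls is empty")
  }
  n_u <- sum(calls$orf_class == "uORF")
  n_o <- sum(calls$orf_class == "oORF")
  grp <- if (n_u >= 1L && n_o >= 1L) "both"
         else if (n_u >= 1L) "uORF_only"
         else if (n_o >= 1L) "oORF_only"
         else "none"
  data.frame(gene_id = gene_id, tl_length = as.integer(tl_length),
             n_uORF = n_u, n_oORF = n_o,
             n_nte = sum(calls$orf_class == "n_terminal_extension"),
             n_nostop = sum(calls$orf_class == "no_stop_in_window"),
             has_uORF = n_u >= 1L, has_oORF = n_o >= 1L,
             group = grp, stringsAsFactors = FALSE)
}

#' Scan a whole cohort and summarize per gene
#'
#' @param cohort a [tl_cohort()].
#' @param window downstream search window in nt (see [scan_transcript()]).
#' @return list with `calls` (row-bound call table) and `summaries` (one row
#'   per gene, in cohort order, with an extra `tl_has_N` flag for leaders
#'   containing ambiguous bases).
#' @export
scan_cohort <- function(cohort, window = 300L) {
  stopifnot(inherits(cohort, "tl_cohort"))
  call_list <- vector("list", length(cohort))
  summ_list <- vector("list", length(cohort))
  for (k in seq_along(cohort)) {
    rec <- cohort[[k]]
    calls <- scan_transcript(rec, window = window)
    call_list[[k]] <- calls
    s <- summarize_gene(calls, rec$tl_length, gene_id = rec$gene_id)
    s$tl_has_N <- grepl("N", rec$tl_seq, fixed = TRUE)
    summ_list[[k]] <- s
  }
  list(calls = do.call(rbind, c(list(.empty_calls()), call_list)),
       summaries = do.call(rbind, summ_list))
}
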