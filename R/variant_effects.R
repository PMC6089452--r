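#' Apply a point substitution to a transcript-leader record
#'
#' Positions use the relative convention (no position 0): negative positions
#' index the TL, positive positions index the downstream/CDS sequence.
#' Substitutions at positions >= +1 are permitted but flagged in the
#' record's warnings (they alter the CDS, as the engineered stop-codon
#' mutations of overlapping ORFs sometimes must).
#'
#' @param record a [tl_record()].
#' @param pos relative coordinate of the base to replace.
#' @param alt replacement base (A/C/G/T).
#' @param ref optional expected reference base; mismatches error.
#' @return the modified [tl_record()].
#' @export
apply_substitution <- function(record, pos, alt, ref = NULL) {
  stopifnot(inherits(record, "tl_record"))
  pos <- as.integer(pos)
  alt <- toupper(alt)
  if (!(alt %in% c("A", "C", "G", "T"))) stop("alt must be one of A,C,G,T")
  if (pos == 0L) stop("no position 0: CDS first base is +1, last TL base is -1")
  L <- record$tl_length
  if (pos < 0L) {
    i <- pos + L + 1L
    if (i < 1L) stop("position ", pos, " lies upstream of the TL (length ",
                     L, ")")
    cur <- substr(record$tl_seq, i, i)
    if (!is.null(ref) && toupper(ref) != cur) {
      stop("reference mismatch at ", pos, ": record has ", cur, ", not ", ref)
    }
    if (cur == alt) {
      record$warnings <- c(record$warnings,
                           sprintf("synonymous_with_reference_at_%d", pos))
      return(record)
    }
    substr(record$tl_seq, i, i) <- alt
  } else {
    if (pos > nchar(record$downstream_seq)) {
      stop("position +", pos, " lies beyond the downstream sequence")
    }
    cur <- substr(record$downstream_seq, pos, pos)
    if (!is.null(ref) && toupper(ref) != cur) {
      stop("reference mismatch at +", pos, ": record has ", cur, ", not ", ref)
    }
    if (cur == alt) {
      record$warnings <- c(record$warnings,
                           sprintf("synonymous_with_reference_at_%d", pos))
      return(record)
    }
    substr(record$downstream_seq, pos, pos) <- alt
    record$warnings <- c(record$warnings,
                         sprintf("cds_change_at_%d", pos))
  }
  record
}

#' Parse a substitution string like "-13A>T"
#'
#' @param spec character vector of substitutions in the form
#'   `<relpos><ref>><alt>`.
#' @return data.frame with columns `pos`, `ref`, `alt`.
#' @export
parse_substitution <- function(spec) {
  m <- regmatches(spec, regexec("^([+-]?[0-9]+)([ACGTacgt])>([ACGTacgt])$",
                                spec))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed substitution spec: ", paste(spec[bad], collapse = ", "),
         " (expected e.g. -13A>T)")
  }
  data.frame(pos = vapply(m, function(x) as.integer(x[2]), integer(1)),
             ref = toupper(vapply(m, `[`, character(1), 3)),
             alt = toupper(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Apply several substitutions, left to right
#'
#' @param record a [tl_record()].
#' @param subs data.frame from [parse_substitution()], or a character
#'   vector of substitution strings.
#' @return the modified [tl_record()].
#' @export
apply_substitutions <- function(record, subs) {
  if (is.character(subs)) subs <- parse_substitution(subs)
  for (k in seq_len(nrow(subs))) {
    record <- apply_substitution(record, subs$pos[k], subs$alt[k],
                                 ref = subs$ref[k])
  }
  record
}

#' Difference between two ORF-call architectures
#'
#' Matches calls between a reference and a mutated scan by their start
#' coordinate (a stop mutation preserves the start; a start mutation
#' destroys the call). Calls present only before are `destroyed`
#' (tag `start_loss`); only after, `created`; calls sharing a start whose
#' stop, class or length changed are `altered`, tagged
#' `stop_loss_extension` when the stop moved downstream (or was lost),
#' `stop_gain_truncation` when it moved upstream (or was gained), plus
#' `class_change` when the class differs.
#'
#' @param before call table for the reference record.
#' @param after call table for the mutated record.
#' @return list of class `architecture_diff` with data.frames `destroyed`,
#'   `created`, `altered` (before/after columns suffixed `_before` /
#'   `_after`, plus `tags`), and `unchanged`.
#' @export
diff_architecture <- function(before, after) {
  gid_b <- unique(before$gene_id); gid_a <- unique(after$gene_id)
  if (length(gid_b) > 1L || length(gid_a) > 1L) {
    stop("call tables must each cover a single gene")
  }
  if (length(gid_b) == 1L && length(gid_a) == 1L && gid_b != gid_a) {
    stop("gene_id mismatch: ", gid_b, " vs ", gid_a)
  }
  only_b <- before[!(before$start %in% after$start), , drop = FALSE]
  only_a <- after[!(after$start %in% before$start), , drop = FALSE]
  if (nrow(only_b)) only_b$tags <- "start_loss"
  shared <- intersect(before$start, after$start)
  alt_rows <- list(); unch_rows <- list()
  for (s in shared) {
    b <- before[before$start == s, , drop = FALSE]
    a <- after[after$start == s, , drop = FALSE]
    same <- identical(b$stop_third_base, a$stop_third_base) &&
      identical(b$orf_class, a$orf_class) &&
      identical(b$length_aa, a$length_aa)
    if (same) {
      unch_rows[[length(unch_rows) + 1L]] <- b
    } else {
      tags <- character(0)
      sb <- b$stop_third_base; sa <- a$stop_third_base
      if ((is.na(sa) && !is.na(sb)) ||
          (!is.na(sb) && !is.na(sa) && sa > sb)) {
        tags <- c(tags, "stop_loss_extension")
      }
      if ((is.na(sb) && !is.na(sa)) ||
          (!is.na(sb) && !is.na(sa) && sa < sb)) {
        tags <- c(tags, "stop_gain_truncation")
      }
      if (b$orf_class != a$orf_class) tags <- c(tags, "class_change")
      row <- data.frame(
        gene_id = b$gene_id, start = b$start,
        stop_third_base_before = sb, stop_third_base_after = sa,
        length_aa_before = b$length_aa, length_aa_after = a$length_aa,
        orf_class_before = b$orf_class, orf_class_after = a$orf_class,
        tags = paste(tags, collapse = ","), stringsAsFactors = FALSE)
      alt_rows[[length(alt_rows) + 1L]] <- row
    }
  }
  structure(
    list(destroyed = only_b, created = only_a,
         altered = if (length(alt_rows)) do.call(rbind, alt_rows) else
           data.frame(),
         unchanged = if (length(unch_rows)) do.call(rbind, unch_rows) else
           .empty_calls()),
    class = "architecture_diff"
  )
}

#' @export
print.architecture_diff <- function(x, ...) {
  cat("<architecture_diff> destroyed:", nrow(x$destroyed),
      " created:", nrow(x$created), " altered:", nrow(x$altered),
      " unchanged:", nrow(x$unchanged), "\n")
  if (nrow(x$altered)) print(x$altered)
  invisible(x)
}

#' Is an architecture diff empty?
#'
#' @param diff an `architecture_diff`.
#' @return TRUE when no calls were created, destroyed, or altered.
#' @export
is_empty_diff <- function(diff) {
  nrow(diff$destroyed) == 0L && nrow(diff$created) == 0L &&
    nrow(diff$altered) == 0L
}
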