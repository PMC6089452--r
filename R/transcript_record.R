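#' Transcript-leader record
#'
#' The unit of scanning: one gene's transcript leader (TL, the 5' UTR read
#' 5'->3') together with the CDS-proximal downstream sequence starting at the
#' first base of the annotated CDS. Sequences are plain uppercase character
#' strings over A, C, G, T, N.
#'
#' @param gene_id gene identifier (opaque string).
#' @param tl_seq TL sequence, length L >= 0 nt.
#' @param downstream_seq sequence starting at the CDS first base, length
#'   W >= 3 nt. A warning is recorded (not raised as an error) when it does
#'   not begin with ATG.
#' @param species_label optional free-text label.
#' @param declared_tl_length optional TL length from an external table;
#'   must equal `nchar(tl_seq)` when supplied.
#' @return an object of class `tl_record`: a list with elements `gene_id`,
#'   `tl_seq`, `downstream_seq`, `species_label`, `tl_length`, and
#'   `warnings` (character vector of validation notes).
#' @export
tl_record <- function(gene_id, tl_seq, downstream_seq, species_label = NULL,
                      declared_tl_length = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  tl_seq <- toupper(as.character(tl_seq))
  downstream_seq <- toupper(as.character(downstream_seq))
  bad <- gsub("[ACGTN]", "", paste0(tl_seq, downstream_seq))
  if (nzchar(bad)) {
    stop("sequence for ", gene_id, " contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  if (nchar(downstream_seq) < 3L) {
    stop("downstream_seq for ", gene_id, " must be at least 3 nt (got ",
         nchar(downstream_seq), ")")
  }
  warns <- character(0)
  if (substr(downstream_seq, 1L, 3L) != "ATG") {
    warns <- c(warns, "downstream_does_not_start_with_ATG")
  }
  if (!is.null(declared_tl_length) &&
      as.integer(declared_tl_length) != nchar(tl_seq)) {
    stop("declared TL length (", declared_tl_length, ") does not match ",
         "tl_seq length (", nchar(tl_seq), ") for ", gene_id)
  }
  structure(
    list(gene_id = gene_id,
         tl_seq = tl_seq,
         downstream_seq = downstream_seq,
         species_label = species_label,
         tl_length = nchar(tl_seq),
         warnings = warns),
    class = "tl_record"
  )
}

#' @export
print.tl_record <- function(x, ...) {
  cat("<tl_record> ", x$gene_id,
      "  TL ", x$tl_length, " nt, downstream ", nchar(x$downstream_seq),
      " nt", sep = "")
  if (length(x$warnings)) cat("  [", paste(x$warnings, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Bundle records into a cohort
#'
#' @param records list of [tl_record()] objects.
#' @param skip_report optional data.frame (gene_id, reason) of records
#'   dropped on the way in.
#' @return list of records with class `tl_cohort` and attribute
#'   `skip_report`.
#' @export
tl_cohort <- function(records, skip_report = NULL) {
  stopifnot(all(vapply(records, inherits, logical(1), "tl_record")))
  if (is.null(skip_report)) {
    skip_report <- data.frame(gene_id = character(0), reason = character(0),
                              stringsAsFactors = FALSE)
  }
  names(records) <- vapply(records, `[[`, character(1), "gene_id")
  structure(records, class = "tl_cohort", skip_report = skip_report)
}

#' @export
print.tl_cohort <- function(x, ...) {
  lens <- vapply(x, `[[`, integer(1), "tl_length")
  cat("<tl_cohort> ", length(x), " genes; TL length median ",
      stats::median(lens), " nt (range ", min(lens), "-", max(lens), ")\n",
      sep = "")
  sk <- attr(x, "skip_report")
  if (NROW(sk)) cat("  skipped on input: ", NROW(sk), " gene(s)\n", sep = "")
  invisible(x)
}

#' @export
`[.tl_cohort` <- function(x, i) {
  tl_cohort(unclass(x)[i], skip_report = attr(x, "skip_report"))
}
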