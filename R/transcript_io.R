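# FASTA header convention for pre-extracted regions: each entry is the
# retrieved region around one gene, with key=value fields after the id,
# e.g. ">YDR082W cds_start=1001 tl_length=49". cds_start is the 1-based
# index of the CDS first base within the entry's own sequence; the TL is
# the tl_length bases immediately 5' of it. tl_length may instead come
# from a TL-length table keyed by gene id.

.hdr_int <- function(x) {
  if (is.null(x)) NA_integer_ else suppressWarnings(as.integer(x))
}

.parse_fasta_header <- function(header) {
  parts <- strsplit(trimws(header), "\\s+")[[1]]
  fields <- list(gene_id = parts[1])
  for (p in parts[-1]) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) fields[[kv[1]]] <- kv[2]
  }
  fields
}

#' Read transcript-leader records from a pre-extracted FASTA file
#'
#' Each FASTA entry holds the region retrieved around one gene (upstream
#' sequence plus CDS) with `cds_start=` in the header; the TL length comes
#' from a `tl_length=` header field or from `tl_table`. Genes without a TL
#' length, without a CDS start, or whose declared TL exceeds the available
#' upstream sequence are skipped and reported (see the `skip_report`
#' attribute of the result).
#'
#' @param path FASTA file.
#' @param tl_table optional mapping gene_id -> TL length (nt): a named
#'   numeric vector or a two-column data.frame.
#' @param window maximum downstream sequence retained past the CDS start
#'   (default 300 nt).
#' @param species_label optional label stored on every record.
#' @return a [tl_cohort()]; skipped genes are recorded in
#'   `attr(, "skip_report")` with reasons `no_cds_start`, `no_tl_length`,
#'   `tl_longer_than_upstream`, or `downstream_too_short`.
#' @export
read_transcript_fasta <- function(path, tl_table = NULL, window = 300L,
                                  species_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) {
                     stop("malformed FASTA in ", path, ": ",
                          conditionMessage(e))
                   })
  tl_map <- .as_tl_map(tl_table)
  records <- list()
  skip_id <- character(0); skip_reason <- character(0)
  for (k in seq_along(seqs)) {
    hdr <- .parse_fasta_header(names(seqs)[k])
    gid <- hdr$gene_id
    seq <- as.character(seqs[[k]])
    cds_start <- .hdr_int(hdr$cds_start)
    if (is.na(cds_start)) {
      skip_id <- c(skip_id, gid); skip_reason <- c(skip_reason, "no_cds_start")
      next
    }
    tl_len <- .hdr_int(hdr$tl_length)
    if (is.na(tl_len) && gid %in% names(tl_map)) tl_len <- tl_map[[gid]]
    if (is.na(tl_len)) {
      skip_id <- c(skip_id, gid); skip_reason <- c(skip_reason, "no_tl_length")
      next
    }
    if (tl_len > cds_start - 1L) {
      skip_id <- c(skip_id, gid)
      skip_reason <- c(skip_reason, "tl_longer_than_upstream")
      next
    }
    down <- substr(seq, cds_start, min(nchar(seq), cds_start + window - 1L))
    if (nchar(down) < 3L) {
      skip_id <- c(skip_id, gid)
      skip_reason <- c(skip_reason, "downstream_too_short")
      next
    }
    records[[length(records) + 1L]] <- tl_record(
      gene_id = gid,
      tl_seq = substr(seq, cds_start - tl_len, cds_start - 1L),
      downstream_seq = down,
      species_label = species_label,
      declared_tl_length = tl_len
    )
  }
  tl_cohort(records,
            skip_report = data.frame(gene_id = skip_id, reason = skip_reason,
                                     stringsAsFactors = FALSE))
}

.as_tl_map <- function(tl_table) {
  if (is.null(tl_table)) return(integer(0))
  if (is.data.frame(tl_table)) {
    stats::setNames(as.integer(tl_table[[2]]), as.character(tl_table[[1]]))
  } else {
    stats::setNames(as.integer(tl_table), names(tl_table))
  }
}

#' Write a cohort back to FASTA with split metadata in the headers
#'
#' Inverse of [read_transcript_fasta()]: each record becomes one entry
#' holding TL + downstream with `cds_start=` and `tl_length=` header fields,
#' so reading the file back reproduces the cohort.
#'
#' @param cohort a [tl_cohort()].
#' @param path output FASTA path.
#' @export
write_transcript_fasta <- function(cohort, path) {
  stopifnot(inherits(cohort, "tl_cohort"))
  seqs <- Biostrings::DNAStringSet(vapply(cohort, function(r) {
    paste0(r$tl_seq, r$downstream_seq)
  }, character(1)))
  names(seqs) <- vapply(cohort, function(r) {
    sprintf("%s cds_start=%d tl_length=%d", r$gene_id, r$tl_length + 1L,
            r$tl_length)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Extract transcript-leader records from a genome FASTA and a feature file
#'
#' Features (one per gene, spanning the CDS/gene body) are read with
#' rtracklayer, which normalizes GFF3 (1-based inclusive) and BED (0-based
#' half-open) coordinates to a common 1-based representation; the format is
#' chosen by file extension unless `dialect` overrides it. For minus-strand
#' genes both sequences are reverse-complemented so every record reads
#' 5'->3'; the downstream sequence is the first `window` nt of the
#' CDS-containing strand from the CDS first base.
#'
#' @param genome FASTA file of contigs.
#' @param features GFF3 or BED file with one feature per gene; gene ids are
#'   taken from the `ID`/`Name`/`gene_id` attribute (GFF3) or the name
#'   column (BED).
#' @param tl_table mapping gene_id -> TL length in nt (named vector or
#'   two-column data.frame). Genes without an entry are skipped.
#' @param window downstream window in nt (default 300).
#' @param dialect "auto" (by extension), "gff3", or "bed".
#' @param species_label optional label stored on every record.
#' @return a [tl_cohort()] with a `skip_report` attribute.
#' @export
extract_records_from_genome <- function(genome, features, tl_table,
                                        window = 300L,
                                        dialect = c("auto", "gff3", "bed"),
                                        species_label = NULL) {
  dialect <- match.arg(dialect)
  contigs <- Biostrings::readDNAStringSet(genome)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- if (dialect == "auto") rtracklayer::import(features)
        else rtracklayer::import(features, format = dialect)
  ids <- .feature_ids(gr)
  tl_map <- .as_tl_map(tl_table)
  records <- list()
  skip_id <- character(0); skip_reason <- character(0)
  skip <- function(gid, why) {
    skip_id <<- c(skip_id, gid); skip_reason <<- c(skip_reason, why)
  }
  for (k in seq_along(gr)) {
    gid <- ids[k]
    if (!(gid %in% names(tl_map))) { skip(gid, "no_tl_length"); next }
    tl_len <- tl_map[[gid]]
    chrom <- as.character(GenomicRanges::seqnames(gr)[k])
    if (!(chrom %in% names(contigs))) { skip(gid, "unknown_contig"); next }
    strand <- as.character(GenomicRanges::strand(gr)[k])
    if (!(strand %in% c("+", "-"))) stop("unknown strand '", strand,
                                         "' for feature ", gid)
    clen <- length(contigs[[chrom]])
    st <- GenomicRanges::start(gr)[k]
    en <- GenomicRanges::end(gr)[k]
    if (strand == "+") {
      tl_from <- st - tl_len; tl_to <- st - 1L
      dn_from <- st; dn_to <- min(clen, st + window - 1L)
      if (tl_from < 1L) { skip(gid, "tl_longer_than_upstream"); next }
      tl <- as.character(Biostrings::subseq(contigs[[chrom]], tl_from, tl_to))
      dn <- as.character(Biostrings::subseq(contigs[[chrom]], dn_from, dn_to))
    } else {
      tl_from <- en + 1L; tl_to <- en + tl_len
      dn_from <- max(1L, en - window + 1L); dn_to <- en
      if (tl_to > clen) { skip(gid, "tl_longer_than_upstream"); next }
      rc <- function(from, to) {
        as.character(Biostrings::reverseComplement(
          Biostrings::subseq(contigs[[chrom]], from, to)))
      }
      tl <- rc(tl_from, tl_to)
      dn <- rc(dn_from, dn_to)
    }
    if (nchar(dn) < 3L) { skip(gid, "downstream_too_short"); next }
    records[[length(records) + 1L]] <-
      tl_record(gid, tl, dn, species_label = species_label,
                declared_tl_length = tl_len)
  }
  tl_cohort(records,
            skip_report = data.frame(gene_id = skip_id, reason = skip_reason,
                                     stringsAsFactors = FALSE))
}

.feature_ids <- function(gr) {
  md <- GenomicRanges::mcols(gr)
  for (col in c("ID", "Name", "gene_id", "name")) {
    if (col %in% names(md) && !all(is.na(md[[col]]))) {
      return(as.character(md[[col]]))
    }
  }
  paste0("feature_", seq_along(gr))
}

#' Write ORF calls to a TSV table
#'
#' Columns `gene`, `start`, `stop`, `class`, `length_aa`, `frame_offset`.
#' `start` is the relative position of the uAUG first base and `stop` the
#' relative position of the third base of the stop codon (NA when no stop
#' was found in the window), both counted with CDS first base = +1 and last
#' TL base = -1.
#'
#' @param calls call table from [scan_transcript()] / [scan_cohort()].
#' @param path output path.
#' @export
write_orf_table <- function(calls, path) {
  out <- data.frame(gene = calls$gene_id, start = calls$start,
                    stop = calls$stop_third_base, class = calls$orf_class,
                    length_aa = calls$length_aa,
                    frame_offset = calls$frame_offset)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ORF-call table written by [write_orf_table()]
#'
#' @param path TSV path.
#' @return call table in the in-memory layout of [scan_transcript()].
#' @export
read_orf_table <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "integer"))
  data.frame(gene_id = tb$gene, start = tb$start,
             stop_third_base = tb$stop, length_aa = tb$length_aa,
             frame_offset = tb$frame_offset, orf_class = tb$class,
             stringsAsFactors = FALSE)
}

#' Read a two-column protein-abundance table
#'
#' Two tab-separated columns, gene id and abundance (linear units); a
#' header line is detected and skipped automatically. Non-numeric or
#' missing abundances are dropped with a count; duplicated gene ids keep
#' the last value with a warning.
#'
#' @param path TSV path.
#' @return named numeric vector gene_id -> abundance, with attribute
#'   `n_dropped`.
#' @export
read_abundance_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty abundance table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first_val <- suppressWarnings(as.numeric(fields[[1]][2]))
  if (is.na(first_val)) fields <- fields[-1]  # header line
  ids <- vapply(fields, `[`, character(1), 1)
  vals <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  keep <- !is.na(vals)
  n_dropped <- sum(!keep)
  ids <- ids[keep]; vals <- vals[keep]
  if (length(vals) == 0L) stop("empty abundance table: no numeric rows in ",
                               path)
  if (anyDuplicated(ids)) {
    warning("duplicated gene ids in ", path, "; keeping the last value")
    last <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[last]; vals <- vals[last]
  }
  structure(stats::setNames(vals, ids), n_dropped = n_dropped)
}

#' Read a TL-length table (gene id, TL length in nt)
#'
#' @param path two-column TSV, header optional.
#' @return named integer vector gene_id -> TL length.
#' @export
read_tl_table <- function(path) {
  ab <- read_abundance_table(path)
  stats::setNames(as.integer(ab), names(ab))
}
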