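#' Load a real (user-downloaded) transcript cohort
#'
#' The genome-scale comparisons and the real STN1 worked examples run on
#' externally retrieved sequence sets that are not distributed with the
#' package. This loader expects, under `dir`:
#'
#' * `<species>_regions.fasta` - per-gene regions (upstream sequence + CDS)
#'   with `cds_start=` headers, as produced by
#'   [extract_records_from_genome()] / [write_transcript_fasta()] from a
#'   genome + annotation download (e.g. YeastMine or Ensembl Biomart
#'   exports);
#' * `<species>_tl_lengths.tsv` - gene id and TL length (nt), using the
#'   longest reported isoform per gene.
#'
#' @param dir directory holding the downloaded files.
#' @param species label used in the file names (e.g. "yeast", "human").
#' @param window downstream window in nt.
#' @return a [tl_cohort()].
#' @export
load_real_cohort <- function(dir, species, window = 300L) {
  fa <- file.path(dir, paste0(species, "_regions.fasta"))
  tl <- file.path(dir, paste0(species, "_tl_lengths.tsv"))
  missing <- c(fa, tl)[!file.exists(c(fa, tl))]
  if (length(missing)) {
    stop("real ", species, " cohort not available: missing ",
         paste(missing, collapse = ", "),
         ". These files must be assembled from an external annotation ",
         "download (see the package README); they are not bundled.")
  }
  read_transcript_fasta(fa, tl_table = read_tl_table(tl), window = window,
                        species_label = species)
}
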