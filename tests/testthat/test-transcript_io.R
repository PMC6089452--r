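write_lines <- function(lines, path) writeLines(lines, path)

test_that("pre-extracted FASTA is split into TL and downstream", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  seq400 <- paste(rep(c("A", "C", "G", "T"), 100), collapse = "")
  write_lines(c(">g1 cds_start=101 tl_length=49", seq400), fa)
  co <- suppressWarnings(read_transcript_fasta(fa))
  expect_length(co, 1L)
  expect_equal(co[["g1"]]$tl_length, 49L)
  expect_equal(nchar(co[["g1"]]$downstream_seq), 300L)
  expect_equal(co[["g1"]]$tl_seq, substr(seq400, 52, 100))
  expect_equal(co[["g1"]]$downstream_seq, substr(seq400, 101, 400))
})

test_that("TL lengths can come from a table; unknown genes are skipped", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  s <- strrep("ACGT", 60)
  write_lines(c(">known cds_start=121", s,
                ">unknown cds_start=121", s,
                ">toolong cds_start=121", s), fa)
  co <- suppressWarnings(read_transcript_fasta(
    fa, tl_table = c(known = 50, toolong = 150)))
  expect_length(co, 1L)
  expect_equal(names(co), "known")
  sk <- attr(co, "skip_report")
  expect_equal(nrow(sk), 2L)
  expect_equal(sk$reason[sk$gene_id == "unknown"], "no_tl_length")
  expect_equal(sk$reason[sk$gene_id == "toolong"], "tl_longer_than_upstream")
})

test_that("cohort FASTA round trip preserves sequences exactly", {
  g <- generate_cohort(15, preset = "yeast", mode = "iid", seed = 2)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_transcript_fasta(g$cohort, fa)
  back <- read_transcript_fasta(fa)
  expect_equal(names(back), names(g$cohort))
  for (id in names(back)) {
    expect_equal(back[[id]]$tl_seq, g$cohort[[id]]$tl_seq)
    expect_equal(back[[id]]$downstream_seq, g$cohort[[id]]$downstream_seq)
  }
})

test_that("genome extraction honors strand and dialect", {
  contig <- paste(c(rep("C", 10), "A", "T", "G", "T", "A", "A", "C", "C",
                    strsplit(strrep("GATTACA", 6), "")[[1]]), collapse = "")
  genome <- withr::local_tempfile(fileext = ".fasta")
  write_lines(c(">chr1 test contig", contig), genome)
  # plus-strand gene: CDS starts at position 21 (1-based), TL length 10
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_lines(c("##gff-version 3",
                paste("chr1", "test", "gene", "21", "45", ".", "+", ".",
                      "ID=plus_gene", sep = "\t")), gff)
  co <- suppressWarnings(extract_records_from_genome(
    genome, gff, c(plus_gene = 10), window = 20))
  expect_equal(co[["plus_gene"]]$tl_seq, substr(contig, 11, 20))
  expect_equal(co[["plus_gene"]]$downstream_seq, substr(contig, 21, 40))

  # the same interval as BED (0-based half-open) gives identical records
  bed <- withr::local_tempfile(fileext = ".bed")
  write_lines(paste("chr1", "20", "45", "plus_gene", "0", "+", sep = "\t"),
              bed)
  co_bed <- suppressWarnings(extract_records_from_genome(
    genome, bed, c(plus_gene = 10), window = 20))
  expect_equal(co_bed[["plus_gene"]]$tl_seq, co[["plus_gene"]]$tl_seq)
  expect_equal(co_bed[["plus_gene"]]$downstream_seq,
               co[["plus_gene"]]$downstream_seq)

  # minus-strand gene ending at position 30: TL is the reverse complement
  # of the 10 bases 3' of the CDS start on the forward strand
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_lines(c("##gff-version 3",
                paste("chr1", "test", "gene", "11", "30", ".", "-", ".",
                      "ID=minus_gene", sep = "\t")), gff2)
  co2 <- suppressWarnings(extract_records_from_genome(
    genome, gff2, c(minus_gene = 8), window = 20))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(co2[["minus_gene"]]$tl_seq, rc(substr(contig, 31, 38)))
  expect_equal(co2[["minus_gene"]]$downstream_seq, rc(substr(contig, 11, 30)))

  # TL running off the contig is skipped with a reason
  co3 <- suppressWarnings(extract_records_from_genome(
    genome, gff, c(plus_gene = 25), window = 20))
  expect_length(co3, 0L)
  expect_equal(attr(co3, "skip_report")$reason, "tl_longer_than_upstream")
})

test_that("ORF tables round-trip through TSV, including NA stops", {
  r <- rec("ATGCC", "ATGGGGGGG")
  calls <- rbind(scan_transcript(rec("ATGTAACC", "ATGGGGTAA")),
                 scan_transcript(r, window = 9L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_orf_table(calls, tsv)
  back <- read_orf_table(tsv)
  expect_equal(back, calls, ignore_attr = TRUE)
  expect_true(is.na(back$stop_third_base[2]))
  header <- readLines(tsv, n = 1)
  expect_equal(header, "gene\tstart\tstop\tclass\tlength_aa\tframe_offset")
  # empty call list -> header-only file
  write_orf_table(scan_transcript(rec("CCCCCC")), tsv)
  expect_equal(length(readLines(tsv)), 1L)
})

test_that("abundance tables are parsed with drops and duplicates handled", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("g1\t100", "g2\t5"), tsv)
  ab <- read_abundance_table(tsv)
  expect_equal(ab, c(g1 = 100, g2 = 5), ignore_attr = TRUE)

  write_lines(c("gene\tabundance", "g1\t100", "g3\tNA", "g2\t5"), tsv)
  ab <- read_abundance_table(tsv)
  expect_equal(names(ab), c("g1", "g2"))
  expect_equal(attr(ab, "n_dropped"), 1L)

  write_lines(c("g1\t100", "g1\t7"), tsv)
  expect_warning(ab <- read_abundance_table(tsv), "duplicated")
  expect_equal(unname(ab["g1"]), 7)

  write_lines(c("gene\tabundance", "g1\tnot_a_number"), tsv)
  expect_error(read_abundance_table(tsv), "empty abundance table")
})
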