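test_that("hand-traced scans recover the expected calls", {
  # uORF completed wholly within the leader
  calls <- scan_transcript(rec("ATGTAACC", "ATGGGGTAA"))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, -8L)
  expect_equal(calls$stop_third_base, -3L)
  expect_equal(calls$orf_class, "uORF")
  expect_equal(calls$length_aa, 1L)
  expect_equal(calls$frame_offset, 2L)

  # stop codon straddling the TL/CDS boundary -> oORF
  calls <- scan_transcript(rec("ATGCC", "ATGACCC"))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, -5L)
  expect_equal(calls$stop_third_base, 4L)
  expect_equal(calls$orf_class, "oORF")
  expect_equal(calls$length_aa, 2L)
  expect_equal(calls$frame_offset, 2L)

  # no AUG, empty TL
  expect_equal(nrow(scan_transcript(rec("CCCCCC"))), 0L)
  expect_equal(nrow(scan_transcript(rec(""))), 0L)
})

test_that("a stop whose third base is the CDS first base gives an oORF", {
  # AUG at -8 (offset 2), codons ATG | CCC | TA+A: stop third base = +1
  calls <- scan_transcript(rec("ATGCCCTA", "ATGGGGTAA"))
  expect_equal(calls$orf_class, "oORF")
  expect_equal(calls$stop_third_base, 1L)
  expect_equal(calls$length_aa, 2L)
})

test_that("in-frame AUGs without a leader stop are N-terminal extensions", {
  # AUG at -6, offset 0, no stop in the TL
  calls <- scan_transcript(rec("ATGCCC", "ATGGGGTAA"))
  expect_equal(calls$orf_class, "n_terminal_extension")
  expect_equal(calls$frame_offset, 0L)
  # same AUG with an in-frame leader stop is a uORF even at offset 0
  calls <- scan_transcript(rec("ATGTAA", "ATGGGGTAA"))
  expect_equal(calls$orf_class, "uORF")
})

test_that("out-of-frame AUGs with no reachable stop are open-ended", {
  calls <- scan_transcript(rec("ATGCC", "ATGGGGGGG"), window = 9L)
  expect_equal(calls$orf_class, "no_stop_in_window")
  expect_true(is.na(calls$stop_third_base))
})

test_that("codons containing N match neither AUG nor stop", {
  expect_equal(nrow(scan_transcript(rec("ATNGCC"))), 0L)
  # N spoils the first candidate stop; the next in-frame stop is used
  calls <- scan_transcript(rec("ATGTNATAACC", "ATGGGGTAA"))
  expect_equal(calls$orf_class, "uORF")
  expect_equal(calls$stop_third_base, -3L)
  expect_equal(calls$length_aa, 2L)
})

test_that("AUGs straddling the TL/CDS boundary are not called", {
  # the only ATG starts at -2 (A is last TL base, TG in the CDS)
  calls <- scan_transcript(rec("CCCCA", "TGGGGTAA"))
  expect_equal(nrow(calls), 0L)
  # start at -3 is the boundary case that IS called
  calls <- scan_transcript(rec("CCATG", "ATGGGGTAA"))
  expect_equal(calls$start, -3L)
})

test_that("nested AUGs are scanned independently and may share a stop", {
  # two in-frame AUGs, one stop
  calls <- scan_transcript(rec("ATGATGTAACC", "ATGGGGTAA"))
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$start, c(-11L, -8L))
  expect_equal(calls$stop_third_base, c(-3L, -3L))
  expect_equal(calls$length_aa, c(2L, 1L))
  expect_equal(calls$orf_class, c("uORF", "uORF"))
})

test_that("span between start and stop matches 3 x (length_aa + 1)", {
  set.seed(42)
  for (i in 1:200) {
    L <- sample(5:60, 1)
    tl <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    calls <- scan_transcript(rec(tl, "ATGCATTAAGGGTAAGTAACC"))
    ok <- !is.na(calls$stop_third_base)
    expect_equal(rel_span(calls$start[ok], calls$stop_third_base[ok]),
                 3L * (calls$length_aa[ok] + 1L))
    expect_true(all(calls$frame_offset == (-calls$start) %% 3L))
  }
})

test_that("enlarging the window only reclassifies open-ended calls", {
  set.seed(99)
  down <- paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                       prob = c(.3, .2, .2, .3)), collapse = "")
  down <- paste0("ATG", down)
  for (i in 1:100) {
    tl <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    r <- rec(tl, down)
    small <- scan_transcript(r, window = 12L)
    big <- scan_transcript(r, window = 300L)
    expect_equal(big$start, small$start)
    closed <- small$orf_class != "no_stop_in_window"
    expect_equal(big$orf_class[closed], small$orf_class[closed])
    expect_equal(big$stop_third_base[closed], small$stop_third_base[closed])
    expect_true(all(big$orf_class[!closed] %in%
                      c("oORF", "no_stop_in_window")))
  }
})

test_that("scanning is deterministic and order-invariant", {
  g <- generate_cohort(30, preset = "yeast", mode = "iid", seed = 5)
  s1 <- scan_cohort(g$cohort)
  s2 <- scan_cohort(g$cohort)
  expect_identical(s1, s2)
  rev_scan <- scan_cohort(g$cohort[rev(seq_along(g$cohort))])
  of <- observed_fractions(s1$summaries)
  expect_equal(observed_fractions(rev_scan$summaries), of)
})

test_that("summarize_gene groups genes by their call classes", {
  r_both <- rec(paste0("ATGTAA", "CC", "ATGC"), "ATGCCTAAC")
  calls <- scan_transcript(r_both)
  expect_setequal(calls$orf_class, c("uORF", "oORF"))
  s <- summarize_gene(calls, 12L)
  expect_equal(s$group, "both")
  expect_true(s$has_uORF && s$has_oORF)

  s <- summarize_gene(scan_transcript(rec("ATGCCC")), 6L)
  expect_equal(s$group, "none")
  expect_equal(s$n_nte, 1L)

  s <- summarize_gene(scan_transcript(rec("CCCCCC")), 6L, gene_id = "g1")
  expect_equal(s$group, "none")
  expect_equal(s$n_uORF + s$n_oORF + s$n_nte + s$n_nostop, 0L)

  mixed <- rbind(scan_transcript(rec("ATGTAA", id = "a")),
                 scan_transcript(rec("ATGTAA", id = "b")))
  expect_error(summarize_gene(mixed, 6L), "mix")
})
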