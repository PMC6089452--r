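.BASES <- c("A", "C", "G", "T")

# A-free filler: contains no ATG and no stop codon in any frame (every
# start/stop codon contains an A), so planted features are the only ORFs.
.bg <- function(n) {
  if (n <= 0L) return(character(0))
  rep_len(c("C", "T", "G", "C", "G", "T"), n)
}

# k random codons from the composition, none of them a stop
.rand_nonstop_codons <- function(k, comp) {
  out <- character(k)
  need <- seq_len(k)
  while (length(need)) {
    m <- matrix(sample(.BASES, 3L * length(need), replace = TRUE,
                       prob = comp), ncol = 3L)
    c3 <- paste0(m[, 1], m[, 2], m[, 3])
    ok <- !(c3 %in% .STOP_CODONS)
    out[need[ok]] <- c3[ok]
    need <- need[!ok]
  }
  out
}

# CDS-like downstream: ATG, open codons, one in-frame stop at the end of
# the window
.make_downstream <- function(window, comp) {
  n_codon <- max(3L, window %/% 3L)
  paste0("ATG",
         paste(.rand_nonstop_codons(n_codon - 2L, comp), collapse = ""),
         sample(.STOP_CODONS, 1L))
}

.rand_tl <- function(L, comp) {
  if (L == 0L) return("")
  paste(sample(.BASES, L, replace = TRUE, prob = comp), collapse = "")
}

#' Generate a synthetic transcript-leader cohort with known ground truth
#'
#' TL lengths are drawn from a lognormal parameterized by its median;
#' presets reproduce yeast-like (median 49 nt) and human-like (median
#' 173 nt) cohorts. Three modes:
#'
#' * `iid` - leader bases drawn independently from `composition`; no
#'   conditioning, so observed and randomization-expected fractions agree
#'   in expectation (a permutation of an iid sequence is another iid draw).
#' * `planted` - each gene independently receives a uORF (probability
#'   `prevalence_uORF`) and/or an oORF (`prevalence_oORF`) at controlled
#'   positions; every gene is verified by re-scanning and regenerated until
#'   the scan reports exactly the planted architecture (planted genes carry
#'   exactly their planted calls; unplanted genes carry none), giving an
#'   exact truth table.
#' * `depleted` - iid leaders rejection-sampled so that a leader containing
#'   an oORF is kept only with probability `oorf_keep_prob`, creating known
#'   negative selection against oORFs.
#'
#' Downstream sequences start with ATG and carry an in-frame stop at the
#' end of the window, with open random codons in between.
#'
#' @param n number of genes.
#' @param preset "yeast" (median 49 nt, AT-rich) or "human" (median 173 nt,
#'   GC-balanced); overridden by explicit `median_tl` / `composition`.
#' @param median_tl median TL length in nt.
#' @param sdlog lognormal dispersion of TL lengths (default 0.7).
#' @param composition base probabilities over A, C, G, T.
#' @param mode "iid", "planted", or "depleted".
#' @param prevalence_uORF,prevalence_oORF planting probabilities (planted
#'   mode).
#' @param oorf_keep_prob acceptance probability for oORF-containing leaders
#'   (depleted mode; default 0.25).
#' @param window downstream window in nt (default 300).
#' @param seed optional integer seed applied locally.
#' @param max_retries per-gene regeneration bound for planted/depleted
#'   modes (default 200); exceeding it is an error reporting the gene.
#' @return list with `cohort` (a [tl_cohort()]) and `truth`: `flags`
#'   (data.frame gene_id / tl_length / planted_uORF / planted_oORF) and
#'   `calls` (scan-verified planted call table, empty for iid mode), plus
#'   `params`.
#' @export
generate_cohort <- function(n, preset = NULL, median_tl = 49, sdlog = 0.7,
                            composition = NULL,
                            mode = c("iid", "planted", "depleted"),
                            prevalence_uORF = 0.3, prevalence_oORF = 0.2,
                            oorf_keep_prob = 0.25, window = 300L,
                            seed = NULL, max_retries = 200L) {
  mode <- match.arg(mode)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("yeast", "human"))
    if (preset == "yeast") {
      median_tl <- 49
      if (is.null(composition)) composition <- c(0.31, 0.19, 0.17, 0.33)
    } else {
      median_tl <- 173
      if (is.null(composition)) composition <- c(0.22, 0.28, 0.28, 0.22)
    }
  }
  if (is.null(composition)) composition <- c(0.31, 0.19, 0.17, 0.33)
  stopifnot(length(composition) == 4L, abs(sum(composition) - 1) < 1e-9,
            prevalence_uORF >= 0, prevalence_uORF <= 1,
            prevalence_oORF >= 0, prevalence_oORF <= 1)
  run <- function() {
    lens <- pmax(1L, as.integer(round(stats::rlnorm(
      n, meanlog = log(median_tl), sdlog = sdlog))))
    plant_u <- if (mode == "planted") stats::runif(n) < prevalence_uORF
               else rep(FALSE, n)
    plant_o <- if (mode == "planted") stats::runif(n) < prevalence_oORF
               else rep(FALSE, n)
    records <- vector("list", n)
    call_rows <- list()
    for (g in seq_len(n)) {
      gid <- sprintf("synth_%05d", g)
      if (mode == "iid") {
        records[[g]] <- tl_record(gid, .rand_tl(lens[g], composition),
                                  .make_downstream(window, composition))
      } else if (mode == "depleted") {
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          tl <- .rand_tl(lens[g], composition)
          down <- .make_downstream(window, composition)
          if (any(.scan_core(tl, down, window)$orf_class == "oORF") &&
              stats::runif(1) > oorf_keep_prob) next
          ok <- TRUE
          break
        }
        if (!ok) stop("retry bound exceeded for gene ", gid,
                      " (depleted mode, L=", lens[g], ")")
        records[[g]] <- tl_record(gid, tl, down)
      } else {
        res <- .plant_gene(gid, lens[g], composition, plant_u[g], plant_o[g],
                           window, max_retries)
        records[[g]] <- res$record
        if (nrow(res$calls)) call_rows[[length(call_rows) + 1L]] <- res$calls
      }
    }
    cohort <- tl_cohort(records)
    flags <- data.frame(
      gene_id = vapply(records, `[[`, character(1), "gene_id"),
      tl_length = vapply(records, `[[`, integer(1), "tl_length"),
      planted_uORF = plant_u, planted_oORF = plant_o,
      stringsAsFactors = FALSE)
    list(cohort = cohort,
         truth = list(flags = flags,
                      calls = do.call(rbind,
                                      c(list(.empty_calls()), call_rows))),
         params = list(mode = mode, median_tl = median_tl, sdlog = sdlog,
                       composition = composition, window = window,
                       prevalence_uORF = prevalence_uORF,
                       prevalence_oORF = prevalence_oORF,
                       oorf_keep_prob = oorf_keep_prob, seed = seed))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# Destroy every ATG in a base vector by resampling its middle base to a
# non-T base. Replacing the middle T cannot create a new ATG (a created
# ATG would need the new base to be T, or a neighboring T that the
# original ATG excludes), so one pass leaves the vector ATG-free.
.scrub_atg <- function(tlv, comp) {
  s <- paste(tlv, collapse = "")
  m <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  if (m[1L] != -1L) {
    p <- comp[-4L] / sum(comp[-4L])  # A, C, G
    tlv[m + 1L] <- sample(c("A", "C", "G"), length(m), TRUE, p)
  }
  tlv
}

# Plant the requested architecture into one gene and verify by re-scan;
# regenerate on any collision (accidental AUGs in planted segments, early
# stops, no reachable downstream stop, ...). The background is scrubbed of
# AUGs first so the planted features are the only initiation sites.
.plant_gene <- function(gid, L, comp, want_u, want_o, window, max_retries) {
  if (want_u && want_o) L <- max(L, 48L)
  else if (want_u) L <- max(L, 24L)
  else if (want_o) L <- max(L, 12L)
  for (try in seq_len(max_retries)) {
    tlv <- .scrub_atg(strsplit(.rand_tl(L, comp), "")[[1]], comp)
    down <- .make_downstream(window, comp)
    o_nt <- 0L
    if (want_o) {
      fo <- sample(1:2, 1L)
      j <- sample(seq_len(min((L - fo) %/% 3L, 8L)), 1L)
      o_nt <- 3L * j + fo
      tlv[(L - o_nt + 1L):L] <-
        c("A", "T", "G", sample(.BASES, o_nt - 3L, TRUE, comp))
      o_start <- -o_nt
    }
    if (want_u) {
      k_aa <- sample(2:6, 1L)
      u_nt <- 3L * (k_aa + 1L)
      avail <- L - o_nt
      if (avail < u_nt) next
      u_idx <- sample(seq_len(avail - u_nt + 1L), 1L)
      tlv[u_idx:(u_idx + u_nt - 1L)] <-
        c("A", "T", "G",
          unlist(strsplit(.rand_nonstop_codons(k_aa - 1L, comp), "")),
          unlist(strsplit(sample(.STOP_CODONS, 1L), "")))
      u_start <- u_idx - L - 1L
    }
    tl <- paste(tlv, collapse = "")
    sc <- .scan_core(tl, down, window)
    n_want <- want_u + want_o
    if (length(sc$start) != n_want) next
    ok <- TRUE
    if (want_u) {
      k <- which(sc$start == u_start)
      ok <- ok && length(k) == 1L && sc$orf_class[k] == "uORF" &&
        sc$length_aa[k] == k_aa
    }
    if (want_o) {
      k <- which(sc$start == o_start)
      ok <- ok && length(k) == 1L && sc$orf_class[k] == "oORF"
    }
    if (!ok) next
    calls <- if (n_want > 0L) {
      data.frame(gene_id = rep(gid, n_want), start = sc$start,
                 stop_third_base = sc$stop_third_base,
                 length_aa = sc$length_aa, frame_offset = sc$frame_offset,
                 orf_class = sc$orf_class, stringsAsFactors = FALSE)
    } else .empty_calls()
    return(list(record = tl_record(gid, tl, down), calls = calls))
  }
  stop("retry bound exceeded for gene ", gid, " (planted mode, L=", L,
       ", uORF=", want_u, ", oORF=", want_o, ")")
}

#' STN1-like transcript-leader fixtures
#'
#' Deterministic fixtures reproducing the upstream-ORF architectures of the
#' yeast and human STN1 transcript leaders and their engineered point
#' mutants:
#'
#' * `yeastWT` - a 90-nt TL carrying a 16-amino-acid uORF (uAUG at -78,
#'   stop wholly within the TL) and a 6-amino-acid oORF (uAUG at -17,
#'   frame offset 2) whose TGA stop occupies +2..+4, overlapping the CDS
#'   start codon. Exact offsets are fixture parameters; the class
#'   architecture and lengths are the invariants.
#' * `u1` - yeastWT with the oORF initiation codon knocked out (-17A>T).
#' * `u2` - yeastWT with the uORF initiation codon knocked out (-78A>T).
#' * `s111` - yeastWT with the oORF termination codon disrupted (+4A>C, a
#'   CDS-internal base, as for the natural gene where the oORF stop
#'   overlaps the CDS); the oORF extends from 6 to 32 amino acids, to the
#'   next in-frame stop at +80..+82.
#' * `humanWT` - a 70-nt TL with two out-of-frame uAUGs (-59 and -47)
#'   encoding overlapping 19- and 15-amino-acid oORFs sharing one stop
#'   codon whose third base is the first base of the CDS (+1).
#' * `human_no_oORF` - humanWT with both oORF initiation codons knocked out
#'   (-59A>T, -47A>T).
#'
#' @param kind fixture name.
#' @return list with `record` (a [tl_record()]), `expected_calls` (call
#'   table the scanner must reproduce), `substitutions` (character vector
#'   of the defining substitutions relative to the wild type; empty for
#'   wild types), and `kind`.
#' @examples
#' fx <- stn1_fixture("yeastWT")
#' scan_transcript(fx$record)
#' @export
stn1_fixture <- function(kind = c("yeastWT", "u1", "u2", "s111", "humanWT",
                                  "human_no_oORF")) {
  kind <- match.arg(kind)
  calls_df <- function(gid, start, stop3, len, fo, cls) {
    if (length(start) == 0L) return(.empty_calls())
    data.frame(gene_id = gid, start = start, stop_third_base = stop3,
               length_aa = len, frame_offset = fo, orf_class = cls,
               stringsAsFactors = FALSE)
  }
  if (kind %in% c("yeastWT", "u1", "u2", "s111")) {
    L <- 90L
    tlv <- .bg(L)
    tlv[13:15] <- c("A", "T", "G")                    # uORF uAUG at -78
    tlv[61:63] <- c("T", "A", "A")                    # uORF stop, third at -28
    tlv[64:65] <- c("C", "C")
    tlv[74:76] <- c("A", "T", "G")                    # oORF uAUG at -17
    tlv[89:90] <- c("C", "C")
    dnv <- .bg(300L)
    dnv[1:4] <- c("A", "T", "G", "A")   # CDS start; oORF stop TGA at +2..+4
    dnv[5:6] <- c("C", "C")
    dnv[80:82] <- c("T", "A", "A")      # next in-frame stop on the oORF frame
    dnv[83:84] <- c("C", "C")
    dnv[151:153] <- c("T", "A", "A")    # CDS stop (frame 0)
    dnv[154:155] <- c("C", "C")
    wt <- tl_record("STN1_yeast_synthetic", paste(tlv, collapse = ""),
                    paste(dnv, collapse = ""), species_label = "yeast")
    uorf <- list(start = -78L, stop3 = -28L, len = 16L, fo = 0L)
    oorf <- list(start = -17L, stop3 = 4L, len = 6L, fo = 2L)
    gid <- wt$gene_id
    switch(kind,
      yeastWT = list(
        record = wt,
        expected_calls = calls_df(gid, c(uorf$start, oorf$start),
                                  c(uorf$stop3, oorf$stop3),
                                  c(uorf$len, oorf$len),
                                  c(uorf$fo, oorf$fo), c("uORF", "oORF")),
        substitutions = character(0), kind = kind),
      u1 = list(
        record = apply_substitutions(wt, "-17A>T"),
        expected_calls = calls_df(gid, uorf$start, uorf$stop3, uorf$len,
                                  uorf$fo, "uORF"),
        substitutions = "-17A>T", kind = kind),
      u2 = list(
        record = apply_substitutions(wt, "-78A>T"),
        expected_calls = calls_df(gid, oorf$start, oorf$stop3, oorf$len,
                                  oorf$fo, "oORF"),
        substitutions = "-78A>T", kind = kind),
      s111 = list(
        record = apply_substitutions(wt, "+4A>C"),
        expected_calls = calls_df(gid, c(uorf$start, oorf$start),
                                  c(uorf$stop3, 82L), c(uorf$len, 32L),
                                  c(uorf$fo, oorf$fo), c("uORF", "oORF")),
        substitutions = "+4A>C", kind = kind))
  } else {
    L <- 70L
    tlv <- .bg(L)
    tlv[12:14] <- c("A", "T", "G")      # 19-aa oORF uAUG at -59
    tlv[24:26] <- c("A", "T", "G")      # 15-aa oORF uAUG at -47
    tlv[69:70] <- c("T", "A")           # shared stop TAA at -2,-1,+1
    dnv <- .bg(300L)
    dnv[1:3] <- c("A", "T", "G")
    dnv[4:5] <- c("C", "C")
    dnv[151:153] <- c("T", "A", "A")    # CDS stop (frame 0)
    dnv[154:155] <- c("C", "C")
    wt <- tl_record("STN1_human_synthetic", paste(tlv, collapse = ""),
                    paste(dnv, collapse = ""), species_label = "human")
    gid <- wt$gene_id
    switch(kind,
      humanWT = list(
        record = wt,
        expected_calls = calls_df(gid, c(-59L, -47L), c(1L, 1L),
                                  c(19L, 15L), c(2L, 2L),
                                  c("oORF", "oORF")),
        substitutions = character(0), kind = kind),
      human_no_oORF = list(
        record = apply_substitutions(wt, c("-59A>T", "-47A>T")),
        expected_calls = .empty_calls(),
        substitutions = c("-59A>T", "-47A>T"), kind = kind))
  }
}

#' Generate synthetic protein abundances with a planted oORF effect
#'
#' Log-normal abundances: log10 values are drawn from
#' N(`base_log10_mean`, `sd`), with the mean shifted down by `delta_oORF`
#' for oORF_only genes. Setting `delta_oORF = 0` gives exchangeable groups
#' (the null).
#'
#' @param summaries per-gene summary table from [scan_cohort()] (its
#'   `group` column determines which genes are shifted).
#' @param base_log10_mean baseline mean of log10 abundance (default 3,
#'   i.e. ~1000 in linear units).
#' @param sd standard deviation of log10 abundance (> 0; default 0.5).
#' @param delta_oORF planted decrement of the log10 mean for oORF_only
#'   genes (default 1).
#' @param seed optional integer seed applied locally.
#' @return named numeric vector gene_id -> abundance (linear units), with
#'   attribute `truth` recording the planted parameters.
#' @export
generate_abundance <- function(summaries, base_log10_mean = 3, sd = 0.5,
                               delta_oORF = 1, seed = NULL) {
  stopifnot(sd > 0)
  run <- function() {
    mu <- rep(base_log10_mean, nrow(summaries))
    mu[summaries$group == "oORF_only"] <- base_log10_mean - delta_oORF
    structure(
      stats::setNames(10^stats::rnorm(nrow(summaries), mu, sd),
                      summaries$gene_id),
      truth = list(base_log10_mean = base_log10_mean, sd = sd,
                   delta_oORF = delta_oORF))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
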