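#' Permute the bases of a transcript leader
#'
#' Applies a uniform random permutation (Fisher-Yates, via [sample()]) to the
#' TL bases; the downstream/CDS sequence, gene id and metadata are untouched.
#' oORF classification of the shuffled leader therefore still runs into the
#' genuine CDS sequence. Uses the current RNG state: call [set.seed()] (or
#' pass `seed` to [expected_fractions()]) for reproducibility.
#'
#' @param record a [tl_record()].
#' @return a [tl_record()] with permuted `tl_seq`.
#' @export
shuffle_leader <- function(record) {
  stopifnot(inherits(record, "tl_record"))
  if (record$tl_length > 1L) {
    record$tl_seq <- paste(sample(strsplit(record$tl_seq, "")[[1]]),
                           collapse = "")
  }
  record
}

#' Randomization-expected uORF/oORF fractions for a cohort
#'
#' For each replicate, every TL in the cohort is individually permuted once
#' and rescanned; the fraction of genes with at least one uORF and with at
#' least one oORF is recorded. The default of a single randomization mirrors
#' the common design for this null; `n_rand >= 10` with mean +/- sd is
#' recommended for stable expected fractions.
#'
#' @param cohort a [tl_cohort()].
#' @param n_rand number of independent randomization replicates (default 1).
#' @param window downstream stop-search window in nt.
#' @param seed optional integer seed applied locally.
#' @return list with `n_genes`, `replicates` (data.frame rep /
#'   frac_uORF / frac_oORF), `frac_uORF_exp`, `frac_oORF_exp` (means),
#'   `sd_uORF`, `sd_oORF`, and `gene_presence`, a data.frame with one row
#'   per gene x replicate (gene_id, tl_length, rep, has_uORF, has_oORF) used
#'   by the length-stratified statistics.
#' @export
expected_fractions <- function(cohort, n_rand = 1L, window = 300L,
                               seed = NULL) {
  stopifnot(inherits(cohort, "tl_cohort"))
  if (length(cohort) == 0L) stop("empty cohort")
  run <- function() {
    gid <- character(0); tll <- integer(0)
    repn <- integer(0); hu <- logical(0); ho <- logical(0)
    n <- length(cohort)
    gid <- vapply(cohort, `[[`, character(1), "gene_id")
    tll <- vapply(cohort, `[[`, integer(1), "tl_length")
    pres_u <- matrix(FALSE, n, n_rand)
    pres_o <- matrix(FALSE, n, n_rand)
    for (r in seq_len(n_rand)) {
      for (k in seq_len(n)) {
        rec <- cohort[[k]]
        tl <- rec$tl_seq
        if (nchar(tl) > 1L) {
          tl <- paste(sample(strsplit(tl, "")[[1]]), collapse = "")
        }
        stopifnot(nchar(tl) == rec$tl_length)  # length preserved
        core <- .scan_core(tl, rec$downstream_seq, window)
        pres_u[k, r] <- any(core$orf_class == "uORF")
        pres_o[k, r] <- any(core$orf_class == "oORF")
      }
    }
    reps <- data.frame(rep = seq_len(n_rand),
                       frac_uORF = colMeans(pres_u),
                       frac_oORF = colMeans(pres_o))
    gp <- data.frame(gene_id = rep(gid, n_rand),
                     tl_length = rep(tll, n_rand),
                     rep = rep(seq_len(n_rand), each = n),
                     has_uORF = as.vector(pres_u),
                     has_oORF = as.vector(pres_o),
                     stringsAsFactors = FALSE)
    list(n_genes = n,
         replicates = reps,
         frac_uORF_exp = mean(reps$frac_uORF),
         frac_oORF_exp = mean(reps$frac_oORF),
         sd_uORF = stats::sd(reps$frac_uORF),
         sd_oORF = stats::sd(reps$frac_oORF),
         gene_presence = gp)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# Symbol coding used by the automaton: A=0, C=1, G=2, T=3; 4 = "no base yet"
# in the two-base memory. Per reading frame a 4-state ORF status:
# 0 closed / no uORF yet, 1 open / no uORF yet, 2 closed / uORF found,
# 3 open / uORF found. A full state is (mem2, mem1, s0, s1, s2).
.dp_states <- function() {
  g <- expand.grid(s2 = 0:3, s1 = 0:3, s0 = 0:3, m1 = 0:4, m2 = 0:4)
  g$id <- seq_len(nrow(g))
  g
}

.dp_state_id <- function(m2, m1, s0, s1, s2) {
  # must match the ordering of .dp_states()
  ((m2 * 5L + m1) * 4L + s0) * 16L + s1 * 4L + s2 + 1L
}

# Transition matrices, one per phase (which frame's codon completes at the
# incoming position), for a given base composition.
.dp_transitions <- function(base_probs) {
  st <- .dp_states()
  n_state <- nrow(st)
  mats <- vector("list", 3L)
  for (f in 0:2) {
    from <- integer(0); to <- integer(0); pr <- numeric(0)
    for (b in 0:3) {
      is_atg <- st$m2 == 0L & st$m1 == 3L & b == 2L
      is_stop <- st$m2 == 3L &
        ((st$m1 == 0L & (b == 0L | b == 2L)) | (st$m1 == 2L & b == 0L))
      scol <- paste0("s", f)
      s <- st[[scol]]
      snew <- s
      snew[is_atg & (s == 0L | s == 2L)] <- s[is_atg & (s == 0L | s == 2L)] + 1L
      snew[is_stop & (s == 1L | s == 3L)] <- 2L
      sall <- list(st$s0, st$s1, st$s2)
      sall[[f + 1L]] <- snew
      tid <- .dp_state_id(st$m1, rep(b, n_state),
                          sall[[1L]], sall[[2L]], sall[[3L]])
      from <- c(from, st$id)
      to <- c(to, tid)
      pr <- c(pr, rep(base_probs[b + 1L], n_state))
    }
    mats[[f + 1L]] <- Matrix::sparseMatrix(i = to, j = from, x = pr,
                                           dims = c(n_state, n_state))
  }
  mats
}

#' Exact ORF-presence probabilities for an iid random transcript leader
#'
#' Computes, by an exact product-automaton dynamic program, the probability
#' that a transcript leader of length `L` with independently drawn bases
#' contains at least one uORF (AUG-initiated ORF whose stop completes wholly
#' within the leader), at least one oORF (out-of-CDS-frame uAUG whose first
#' in-frame stop does not complete within the leader; the downstream CDS is
#' modeled as eventually supplying a stop with probability 1), and at least
#' one in-frame open uAUG (N-terminal extension).
#'
#' One small automaton per reading frame tracks
#' open/closed x uORF-seen status; the three frames share a two-base memory
#' and are advanced jointly over leader positions, so the result is exact
#' (it accounts for all overlaps and interactions between frames).
#'
#' @param L integer vector of TL lengths (nt).
#' @param base_probs probability vector over A, C, G, T (sums to 1).
#' @return data.frame with columns `L`, `p_uORF`, `p_oORF`, `p_nte`.
#' @examples
#' analytic_presence_prob(c(5, 6), rep(0.25, 4))
#' @export
analytic_presence_prob <- function(L, base_probs = rep(0.25, 4)) {
  stopifnot(all(L >= 0), length(base_probs) == 4L,
            all(base_probs >= 0), all(base_probs <= 1))
  if (abs(sum(base_probs) - 1) > 1e-12) {
    stop("base_probs must sum to 1 (got ", sum(base_probs), ")")
  }
  L <- as.integer(L)
  mats <- .dp_transitions(base_probs)
  st <- .dp_states()
  open_mask <- function(s) s == 1L | s == 3L
  found_mask <- function(s) s >= 2L
  i_uorf <- found_mask(st$s0) | found_mask(st$s1) | found_mask(st$s2)
  i_oorf <- open_mask(st$s1) | open_mask(st$s2)
  i_nte <- open_mask(st$s0)
  out <- data.frame(L = L, p_uORF = NA_real_, p_oORF = NA_real_,
                    p_nte = NA_real_)
  for (j in seq_along(L)) {
    v <- numeric(nrow(st))
    v[.dp_state_id(4L, 4L, 0L, 0L, 0L)] <- 1
    Lj <- L[j]
    if (Lj > 0L) {
      for (p in seq.int(-Lj, -1L)) {
        f <- (2L - p) %% 3L       # frame whose codon ends at position p
        v <- as.numeric(mats[[f + 1L]] %*% v)
      }
    }
    out$p_uORF[j] <- sum(v[i_uorf])
    out$p_oORF[j] <- sum(v[i_oorf])
    out$p_nte[j] <- sum(v[i_nte])
  }
  out
}

#' Brute-force ORF-presence probabilities by exhaustive enumeration
#'
#' Ground-truth oracle for [analytic_presence_prob()]: enumerates all 4^L
#' leaders of length `L`, scans each with the standard scanner against a
#' concrete downstream sequence, and sums the probability mass of sequences
#' containing each class. The default downstream starts with ATG and carries
#' stop codons in every reading frame close to the CDS start, so any ORF
#' still open at the TL/CDS boundary terminates within the window (the
#' regime the analytic model assumes).
#'
#' @param L TL length, at most 10 (4^L sequences are enumerated).
#' @param base_probs probability vector over A, C, G, T.
#' @param downstream downstream/CDS sequence used for every enumerated
#'   leader.
#' @param window stop-search window in nt.
#' @return one-row data.frame: `L`, `p_uORF`, `p_oORF`, `p_nte`,
#'   `p_nostop` (probability mass of leaders with an open-ended call; 0 for
#'   any downstream with stops in all frames within the window).
#' @export
enumerate_presence_prob <- function(L, base_probs = rep(0.25, 4),
                                    downstream = paste0("ATG", strrep("TAAT", 30)),
                                    window = 300L) {
  stopifnot(L >= 0, length(base_probs) == 4L)
  if (L > 10L) stop("L too large to enumerate (max 10)")
  if (abs(sum(base_probs) - 1) > 1e-12) stop("base_probs must sum to 1")
  bases <- c("A", "C", "G", "T")
  if (L == 0L) {
    core <- .scan_core("", downstream, window)
    pres <- table(factor(core$orf_class,
                         levels = c("uORF", "oORF", "n_terminal_extension",
                                    "no_stop_in_window"))) > 0
    return(data.frame(L = 0L, p_uORF = as.numeric(pres[1]),
                      p_oORF = as.numeric(pres[2]),
                      p_nte = as.numeric(pres[3]),
                      p_nostop = as.numeric(pres[4])))
  }
  idx <- as.matrix(expand.grid(rep(list(1:4), L)))
  seqs <- do.call(paste0, as.data.frame(matrix(bases[idx], ncol = L),
                                        stringsAsFactors = FALSE))
  w <- exp(rowSums(matrix(log(base_probs)[idx], ncol = L)))
  p_u <- p_o <- p_n <- p_ns <- 0
  for (s in seq_along(seqs)) {
    if (w[s] == 0) next
    cls <- .scan_core(seqs[s], downstream, window)$orf_class
    if (any(cls == "uORF")) p_u <- p_u + w[s]
    if (any(cls == "oORF")) p_o <- p_o + w[s]
    if (any(cls == "n_terminal_extension")) p_n <- p_n + w[s]
    if (any(cls == "no_stop_in_window")) p_ns <- p_ns + w[s]
  }
  data.frame(L = L, p_uORF = p_u, p_oORF = p_o, p_nte = p_n, p_nostop = p_ns)
}

#' Distinct reading frames used by each ORF class, by exhaustive enumeration
#'
#' Enumerates every length-`L` leader over A/C/G/T, scans each against the
#' given downstream context, and reports which frame offsets occur among
#' calls of each class. uORFs can occupy all three frames while oORFs are
#' confined to the two out-of-CDS frames; this function verifies that law
#' exhaustively.
#'
#' @param L TL length to enumerate (4^L sequences; keep <= 10).
#' @param downstream downstream/CDS context (default an ATG-initiated
#'   sequence with early stops in all frames).
#' @param window stop-search window in nt.
#' @return named list of sorted integer vectors of distinct frame offsets,
#'   one per ORF class.
#' @export
frame_usage_by_enumeration <- function(L,
                                       downstream = "ATGAAGGGTTAAGGTAAGGG",
                                       window = 300L) {
  stopifnot(L >= 1L, L <= 10L)
  bases <- c("A", "C", "G", "T")
  idx <- as.matrix(expand.grid(rep(list(1:4), L)))
  seqs <- do.call(paste0, as.data.frame(matrix(bases[idx], ncol = L),
                                        stringsAsFactors = FALSE))
  seen <- list(uORF = logical(3), oORF = logical(3),
               n_terminal_extension = logical(3),
               no_stop_in_window = logical(3))
  for (s in seqs) {
    core <- .scan_core(s, downstream, window)
    for (k in seq_along(core$orf_class)) {
      cls <- core$orf_class[k]
      seen[[cls]][core$frame_offset[k] + 1L] <- TRUE
    }
  }
  lapply(seen, function(x) which(x) - 1L)
}
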