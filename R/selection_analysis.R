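#' Observed uORF/oORF fractions in a cohort
#'
#' Fraction of genes carrying at least one uORF and at least one oORF; a
#' gene with both contributes to both numerators.
#'
#' @param summaries per-gene summary table from [scan_cohort()].
#' @return list with `n_genes`, `frac_uORF_obs`, `frac_oORF_obs`.
#' @export
observed_fractions <- function(summaries) {
  if (NROW(summaries) == 0L) stop("empty cohort")
  list(n_genes = nrow(summaries),
       frac_uORF_obs = mean(summaries$has_uORF),
       frac_oORF_obs = mean(summaries$has_oORF))
}

#' Combine observed and expected arms into one cohort-fractions object
#'
#' @param obs result of [observed_fractions()].
#' @param exp result of [expected_fractions()] over the same cohort.
#' @return list of class `cohort_fractions` with both arms, replicate
#'   detail, and standard deviations.
#' @export
cohort_fractions <- function(obs, exp) {
  if (obs$n_genes != exp$n_genes) {
    stop("observed and expected arms cover different numbers of genes (",
         obs$n_genes, " vs ", exp$n_genes, ")")
  }
  structure(c(obs, exp[c("frac_uORF_exp", "frac_oORF_exp",
                         "sd_uORF", "sd_oORF", "replicates")]),
            class = "cohort_fractions")
}

#' @export
print.cohort_fractions <- function(x, ...) {
  cat("<cohort_fractions> n =", x$n_genes, "genes\n")
  cat(sprintf("  uORF: observed %.1f%%  expected %.1f%%\n",
              100 * x$frac_uORF_obs, 100 * x$frac_uORF_exp))
  cat(sprintf("  oORF: observed %.1f%%  expected %.1f%%\n",
              100 * x$frac_oORF_obs, 100 * x$frac_oORF_exp))
  invisible(x)
}

.length_bin <- function(tl_length, bin_width) {
  as.integer(floor(tl_length / bin_width)) * as.integer(bin_width)
}

#' Observed and expected fractions stratified by TL length
#'
#' Genes are binned by TL length (default 25-nt bins, left-closed); per bin
#' the observed fraction of genes with uORFs/oORFs and the mean expected
#' fraction over randomization replicates are reported.
#'
#' @param summaries per-gene summary table from [scan_cohort()].
#' @param exp result of [expected_fractions()] over the same cohort (its
#'   `gene_presence` component is used).
#' @param bin_width bin width in nt (default 25).
#' @param min_n bins with fewer genes are flagged `low_support` (default 20).
#' @return data.frame with one row per occupied bin: `bin_start`, `n`,
#'   `frac_uORF_obs`, `frac_oORF_obs`, `frac_uORF_exp`, `frac_oORF_exp`,
#'   `low_support`.
#' @export
length_stratified_fractions <- function(summaries, exp, bin_width = 25L,
                                        min_n = 20L) {
  gp <- exp$gene_presence
  miss <- union(setdiff(summaries$gene_id, gp$gene_id),
                setdiff(gp$gene_id, summaries$gene_id))
  if (length(miss)) {
    stop("observed and expected arms cover different gene sets; differing: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  bin_obs <- .length_bin(summaries$tl_length, bin_width)
  obs <- aggregate(cbind(has_uORF, has_oORF) ~ bin, transform(summaries, bin = bin_obs),
                   FUN = mean)
  nn <- as.data.frame(table(bin = bin_obs), stringsAsFactors = FALSE)
  nn$bin <- as.integer(nn$bin)
  # expected arm: average per-gene presence over replicates, then bin
  gexp <- aggregate(cbind(has_uORF, has_oORF) ~ gene_id + tl_length, gp,
                    FUN = mean)
  gexp$bin <- .length_bin(gexp$tl_length, bin_width)
  expb <- aggregate(cbind(has_uORF, has_oORF) ~ bin, gexp, FUN = mean)
  out <- merge(merge(nn, obs, by = "bin"), expb, by = "bin",
               suffixes = c("_obs", "_exp"))
  out <- out[order(out$bin), ]
  data.frame(bin_start = out$bin, n = out$Freq,
             frac_uORF_obs = out$has_uORF_obs,
             frac_oORF_obs = out$has_oORF_obs,
             frac_uORF_exp = out$has_uORF_exp,
             frac_oORF_exp = out$has_oORF_exp,
             low_support = out$Freq < min_n,
             row.names = NULL)
}

#' Observed/expected ratio curves over TL-length bins
#'
#' Ratio of the observed to the expected fraction per bin for uORFs and
#' oORFs; bins with zero expected fraction give NA. Ratios below 1 indicate
#' depletion relative to composition-matched randomized leaders. The
#' returned object carries a flag noting whether the oORF ratio sits below
#' the uORF ratio in every supported bin beyond `long_from` nt (the
#' signature of stronger selection against oORFs in longer leaders).
#'
#' @param strat stratified table from [length_stratified_fractions()].
#' @param long_from TL length (nt) from which the oORF-below-uORF comparison
#'   is evaluated (default 50).
#' @return data.frame `bin_start`, `n`, `ratio_uORF`, `ratio_oORF`,
#'   `low_support`, with attribute `oORF_below_uORF_beyond` (logical).
#' @export
oe_curve <- function(strat, long_from = 50L) {
  ratio <- function(obs, exp) ifelse(exp > 0, obs / exp, NA_real_)
  out <- data.frame(bin_start = strat$bin_start, n = strat$n,
                    ratio_uORF = ratio(strat$frac_uORF_obs, strat$frac_uORF_exp),
                    ratio_oORF = ratio(strat$frac_oORF_obs, strat$frac_oORF_exp),
                    low_support = strat$low_support)
  sel <- out$bin_start >= long_from & !out$low_support &
    !is.na(out$ratio_uORF) & !is.na(out$ratio_oORF)
  attr(out, "oORF_below_uORF_beyond") <-
    if (any(sel)) all(out$ratio_oORF[sel] < out$ratio_uORF[sel]) else NA
  out
}

#' Tukey box-plot statistics
#'
#' Quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7); whiskers extend to the most extreme data
#' point within 1.5 x IQR of the nearer quartile; points beyond are
#' outliers.
#'
#' @param values numeric sample, n >= 1, no NAs.
#' @return list: `n`, `q1`, `median`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `n_outliers`.
#' @export
box_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("values must be a non-empty numeric vector without NAs")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  inside <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  list(n = length(values), q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       n_outliers = sum(!inside))
}

#' Compare protein abundance between uORF-only and oORF-only genes
#'
#' Joins per-gene summaries with an abundance table, keeps the uORF_only and
#' oORF_only groups (genes with both classes, or neither, are excluded from
#' this comparison), and tests for a difference with a two-sided unpaired
#' t-test. Default is Student's pooled-variance test on untransformed
#' values; Welch and a log10 transform are available.
#'
#' @param summaries per-gene summary table from [scan_cohort()].
#' @param abundance named numeric vector, gene_id -> abundance (linear
#'   units), e.g. from [read_abundance_table()].
#' @param transform "none" or "log10" (applied before testing; non-positive
#'   values are dropped with a count under log10).
#' @param test "student" (pooled variance) or "welch".
#' @return list of class `abundance_comparison`: per-group [box_stats()]
#'   (`uORF_only`, `oORF_only`), group sizes, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `n_missing_abundance`,
#'   `n_dropped_nonpositive`, and the settings used.
#' @export
abundance_association <- function(summaries, abundance,
                                  transform = c("none", "log10"),
                                  test = c("student", "welch")) {
  transform <- match.arg(transform)
  test <- match.arg(test)
  keep <- summaries$group %in% c("uORF_only", "oORF_only")
  s <- summaries[keep, , drop = FALSE]
  ab <- abundance[match(s$gene_id, names(abundance))]
  n_missing <- sum(is.na(ab))
  s <- s[!is.na(ab), , drop = FALSE]
  ab <- ab[!is.na(ab)]
  n_nonpos <- 0L
  if (transform == "log10") {
    bad <- ab <= 0
    n_nonpos <- sum(bad)
    s <- s[!bad, , drop = FALSE]
    ab <- log10(ab[!bad])
  }
  x_u <- ab[s$group == "uORF_only"]
  x_o <- ab[s$group == "oORF_only"]
  for (nm in c("uORF_only", "oORF_only")) {
    if (sum(s$group == nm) < 2L) {
      stop("group ", nm, " has fewer than 2 genes with abundance")
    }
  }
  tt <- stats::t.test(x_u, x_o, var.equal = (test == "student"))
  structure(
    list(uORF_only = box_stats(x_u), oORF_only = box_stats(x_o),
         n_uORF_only = length(x_u), n_oORF_only = length(x_o),
         t_statistic = unname(tt$statistic),
         degrees_of_freedom = unname(tt$parameter),
         p_value = tt$p.value,
         n_missing_abundance = n_missing,
         n_dropped_nonpositive = n_nonpos,
         transform = transform, test = test),
    class = "abundance_comparison"
  )
}

#' @export
print.abundance_comparison <- function(x, ...) {
  cat("<abundance_comparison> ", x$test, " t-test, transform = ",
      x$transform, "\n", sep = "")
  cat(sprintf("  uORF_only (n=%d): median %.3g [Q1 %.3g, Q3 %.3g]\n",
              x$n_uORF_only, x$uORF_only$median, x$uORF_only$q1,
              x$uORF_only$q3))
  cat(sprintf("  oORF_only (n=%d): median %.3g [Q1 %.3g, Q3 %.3g]\n",
              x$n_oORF_only, x$oORF_only$median, x$oORF_only$q1,
              x$oORF_only$q3))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g\n", x$t_statistic,
              x$degrees_of_freedom, x$p_value))
  invisible(x)
}
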