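make_summaries <- function(groups, tl_length = 50L) {
  data.frame(gene_id = sprintf("g%03d", seq_along(groups)),
             tl_length = rep(tl_length, length.out = length(groups)),
             n_uORF = as.integer(groups %in% c("uORF_only", "both")),
             n_oORF = as.integer(groups %in% c("oORF_only", "both")),
             n_nte = rep(0L, length(groups)),
             n_nostop = rep(0L, length(groups)),
             has_uORF = groups %in% c("uORF_only", "both"),
             has_oORF = groups %in% c("oORF_only", "both"),
             group = groups, stringsAsFactors = FALSE)
}

test_that("observed fractions count genes with each class", {
  s <- make_summaries(c("uORF_only", "oORF_only", "both", "none"))
  o <- observed_fractions(s)
  expect_equal(o$frac_uORF_obs, 0.5)
  expect_equal(o$frac_oORF_obs, 0.5)
  o <- observed_fractions(make_summaries(rep("none", 7)))
  expect_equal(o$frac_uORF_obs, 0)
  expect_equal(o$frac_oORF_obs, 0)
  expect_error(observed_fractions(make_summaries(character(0))), "empty")
})

test_that("a single length bin reproduces the cohort fractions", {
  g <- generate_cohort(120, preset = "yeast", mode = "iid", seed = 8)
  sc <- scan_cohort(g$cohort)
  ex <- expected_fractions(g$cohort, n_rand = 2, seed = 9)
  st <- length_stratified_fractions(sc$summaries, ex, bin_width = 10000L)
  expect_equal(nrow(st), 1L)
  o <- observed_fractions(sc$summaries)
  expect_equal(st$frac_uORF_obs, o$frac_uORF_obs)
  expect_equal(st$frac_oORF_obs, o$frac_oORF_obs)
  expect_equal(st$frac_uORF_exp, ex$frac_uORF_exp)
  expect_equal(st$n, 120L)
})

test_that("stratification refuses mismatched gene sets", {
  g <- generate_cohort(30, preset = "yeast", mode = "iid", seed = 8)
  sc <- scan_cohort(g$cohort)
  ex <- expected_fractions(g$cohort, n_rand = 1, seed = 9)
  expect_error(
    length_stratified_fractions(sc$summaries[-1, ], ex),
    "different gene sets")
})

test_that("O/E ratios are 1 when observed equals expected and NA at 0", {
  st <- data.frame(bin_start = c(0L, 25L), n = c(30L, 5L),
                   frac_uORF_obs = c(0.2, 0.1), frac_oORF_obs = c(0.1, 0),
                   frac_uORF_exp = c(0.2, 0.1), frac_oORF_exp = c(0.1, 0),
                   low_support = c(FALSE, TRUE))
  oc <- oe_curve(st)
  expect_equal(oc$ratio_uORF, c(1, 1))
  expect_equal(oc$ratio_oORF[1], 1)
  expect_true(is.na(oc$ratio_oORF[2]))
})

test_that("box statistics follow the Tukey convention", {
  b <- box_stats(c(1, 2, 3, 4, 100))
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 4)
  expect_equal(b$iqr, 2)
  expect_equal(b$whisker_high, 4)  # 100 lies beyond 4 + 1.5*2
  expect_equal(b$n_outliers, 1L)

  b <- box_stats(c(5, 5, 5))
  expect_equal(unlist(b[c("q1", "median", "q3", "whisker_low",
                          "whisker_high")]),
               c(q1 = 5, median = 5, q3 = 5, whisker_low = 5,
                 whisker_high = 5))

  set.seed(10)
  for (i in 1:30) {
    x <- rlnorm(sample(2:200, 1), 3, 1)
    b <- box_stats(x)
    expect_gte(b$whisker_low, min(x))
    expect_lte(b$whisker_high, max(x))
    expect_lte(b$q1, b$median)
    expect_lte(b$median, b$q3)
  }
  expect_error(box_stats(numeric(0)), "non-empty")
})

test_that("the abundance t-test matches the textbook pooled formula", {
  s <- make_summaries(c(rep("uORF_only", 3), rep("oORF_only", 3)))
  ab <- stats::setNames(c(1, 2, 3, 2, 3, 4), s$gene_id)
  cmp <- abundance_association(s, ab, test = "student")
  # independent oracle: pooled two-sample t on {1,2,3} vs {2,3,4}
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(cmp$t_statistic, t_oracle, tolerance = 1e-12)
  expect_equal(cmp$t_statistic, -1.224745, tolerance = 1e-6)
  expect_equal(cmp$degrees_of_freedom, 4)
  expect_equal(cmp$p_value, 2 * pt(t_oracle, 4), tolerance = 1e-12)

  ab_same <- stats::setNames(c(1, 2, 3, 1, 2, 3), s$gene_id)
  cmp <- abundance_association(s, ab_same)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("undersized groups and missing abundances are reported", {
  s <- make_summaries(c("uORF_only", "oORF_only", "oORF_only"))
  ab <- stats::setNames(c(1, 2, 3), s$gene_id)
  expect_error(abundance_association(s, ab), "uORF_only")
  s <- make_summaries(c(rep("uORF_only", 3), rep("oORF_only", 2)))
  ab <- stats::setNames(c(1, 2, 3, 2, 3), s$gene_id)[-1]
  cmp <- abundance_association(s, ab)
  expect_equal(cmp$n_missing_abundance, 1L)
  expect_equal(cmp$n_uORF_only, 2L)
})

test_that("a planted abundance decrement is detected", {
  s <- make_summaries(c(rep("uORF_only", 120), rep("oORF_only", 120),
                        rep("both", 10), rep("none", 10)))
  ab <- generate_abundance(s, base_log10_mean = 3, sd = 0.5,
                           delta_oORF = 1, seed = 31)
  cmp <- abundance_association(s, ab, transform = "log10")
  expect_lt(cmp$p_value, 1e-3)
  expect_lt(cmp$oORF_only$median, cmp$uORF_only$median)
  expect_equal(cmp$n_uORF_only, 120L)  # both/none excluded
})
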