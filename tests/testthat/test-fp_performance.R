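ref_tabs <- load_reference_tables()

test_that("expected counts are proportional to screen-negative sizes", {
  # symmetric case: equal group sizes split the total evenly
  tab <- fp_count_table(tibble::tibble(disease = "A", early = 12,
                                       standard = 8, late = 10),
                        c(early = 100, standard = 100, late = 100))
  e <- expected_counts(tab)
  expect_equal(c(e$exp_early, e$exp_standard, e$exp_late), rep(10, 3))
  # conservation: exact expectations sum to the observed total
  e_ref <- expected_counts(ref_tabs$counts)
  expect_equal(e_ref$exp_early + e_ref$exp_standard + e_ref$exp_late,
               as.numeric(ref_tabs$counts$total), tolerance = 1e-9)
  expect_error(
    expected_counts(fp_count_table(tibble::tibble(disease = "A", early = 0,
                                                  standard = 0, late = 0),
                                   c(early = 1, standard = 1, late = 1))),
    "undefined")
})

test_that("display rounding is nearest integer, ties away from zero", {
  expect_identical(round_half_away(c(21.7, 8.76, 4.52, 0.553, 347.03, 2.5)),
                   c(22, 9, 5, 1, 347, 3))
  expect_identical(round_half_away(-2.5), -3)
})

test_that("count_fp restricts cases and tallies windows with percentages", {
  cases <- tibble::tibble(
    disease = "CTD",
    aabc = c(15L, 30L, 30L, 60L, 30L, 30L, 30L, 200L),
    ga = c(39L, 39L, 39L, 39L, 36L, 39L, 39L, 39L),
    bw = c(3000, 3000, 3000, 3000, 3000, 2000, 3000, 3000),
    tpn = c("no", "no", "no", "no", "no", "no", "yes", "no")
  )
  # one preterm, one low BW and one TPN case are filtered; one case at
  # 200 h is outside the collection range
  expect_message(
    tab <- count_fp(cases, neg_sizes = ref_tabs$neg_sizes),
    "outside")
  expect_identical(c(tab$early, tab$standard, tab$late), c(1L, 2L, 1L))
  expect_equal(c(tab$pct_early, tab$pct_standard, tab$pct_late),
               c(25, 50, 25))
  # all-standard series
  allstd <- tibble::tibble(disease = "X", aabc = rep(30L, 10), ga = 39L,
                           bw = 3000, tpn = "no")
  t2 <- count_fp(allstd, neg_sizes = ref_tabs$neg_sizes)
  expect_identical(c(t2$early, t2$standard, t2$late), c(0L, 10L, 0L))
  expect_equal(c(t2$pct_early, t2$pct_standard, t2$pct_late), c(0, 100, 0))
})

test_that("chi-squared tests match brute-force formula oracles", {
  # hand case: obs (10,10) vs exp (5,15) -> 25/5 + 25/15
  hand <- gof_test(c(10, 10), c(5, 15))
  expect_equal(hand$statistic, 25 / 5 + 25 / 15, tolerance = 1e-10)
  exact <- suppressWarnings(gof_test(c(4, 6, 10), c(4, 6, 10)))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p, 1)
  expect_error(gof_test(c(1, 2), c(0, 3)), "zero")
  expect_warning(gof_test(c(1, 2, 3), c(0.5, 2.5, 3)), "below 5")

  set.seed(77)
  for (i in 1:100) {
    obs <- stats::rpois(3, lambda = 40)
    exp <- stats::runif(3, 10, 60)
    exp <- exp / sum(exp) * sum(obs)
    expect_equal(suppressWarnings(gof_test(obs, exp)$statistic),
                 chisq_oracle(obs, exp), tolerance = 1e-10)
    # category test agrees with stats::chisq.test without correction
    tot <- sum(obs)
    pi <- stats::runif(1, 0.05, 0.95)
    mine <- category_test(obs[1], tot, pi)
    base_p <- suppressWarnings(
      stats::chisq.test(c(obs[1], tot - obs[1]), p = c(pi, 1 - pi)))
    expect_equal(mine$statistic, unname(base_p$statistic), tolerance = 1e-10)
    expect_equal(mine$p, base_p$p.value, tolerance = 1e-10)
  }
  expect_equal(category_test(20, 100, 0.2)$p, 1)
  expect_error(category_test(3, 10, 1), "between 0 and 1")
})

test_that("goodness-of-fit test is calibrated under the null", {
  # multinomial draws with the screen-negative shares as probabilities
  share <- ref_tabs$neg_sizes / sum(ref_tabs$neg_sizes)
  set.seed(101)
  reps <- 2000
  total <- 200
  obs <- stats::rmultinom(reps, total, share)
  exp <- total * share
  stat <- colSums((obs - exp)^2 / exp)
  rej <- mean(stat > stats::qchisq(0.95, df = 2))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("consistency calls follow sign matching gated on significance", {
  # elevated marker, raised level, significant excess -> consistent
  expect_identical(classify_consistency(0.55, "elevated", 51, 35.4,
                                        p_overall = 1e-4)$call, "consistent")
  # decreased marker: raised level predicts a deficit of false positives
  expect_identical(classify_consistency(0.23, "decreased", 44, 102.2,
                                        p_overall = 1e-10)$call, "consistent")
  # significant shift against the predicted direction -> inconsistent
  expect_identical(classify_consistency(-0.26, "elevated", 15, 6.1,
                                        p_overall = 4e-4)$call,
                   "inconsistent")
  # unflagged effect or non-significant enrichment -> indeterminate
  expect_identical(classify_consistency(0.1, "elevated", 50, 20,
                                        p_overall = 1e-6)$call,
                   "indeterminate")
  expect_identical(classify_consistency(0.5, "elevated", 3, 2.6,
                                        p_overall = 0.73)$call,
                   "indeterminate")
})

test_that("the performance table carries counts, stars and calls", {
  perf <- suppressWarnings(
    performance_table(enrichment(ref_tabs$counts), ref_tabs$effects,
                      ref_tabs$panel))
  expect_identical(nrow(perf), 9L)
  ctd <- perf[perf$disease == "CTD", ]
  expect_match(ctd$early, "^44 \\(9\\.3%\\) E: 102")
  expect_identical(ctd$call_early, "consistent")
})
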