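test_that("identical config and seed give a bit-identical cohort", {
  cfg <- generator_config(100, seed = 7,
                          metabolite_specs = default_panel()[c("Phe", "C0")])
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(nrow(a), 100L)
  expect_true(all(a$screen == "negative"))
})

test_that("generated concentrations are strictly positive", {
  cfg <- generator_config(2000, seed = 3)
  co <- generate_cohort(cfg)
  for (m in metabolite_names(co)) expect_true(all(co[[m]] > 0))
})

test_that("zero noise and no shifts reproduce the trajectory exactly", {
  spec <- metabolite_spec("X", "decreasing",
                          params = list(base = 10, amp = 5, rate = 0.05),
                          cv = 0, shifts = NULL)
  cfg <- generator_config(500, seed = 2, metabolite_specs = list(spec))
  co <- generate_cohort(cfg)
  expect_equal(co$X, trajectory_mean(spec, co$aabc), tolerance = 1e-12)
})

test_that("decreasing trajectory shows up in binned sample means", {
  cfg <- generator_config(50000, seed = 9,
                          metabolite_specs = default_panel()[c("Phe")])
  co <- generate_cohort(cfg)
  a <- co$Phe[co$aabc >= 12 & co$aabc <= 17]
  b <- co$Phe[co$aabc >= 42 & co$aabc <= 47]
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  expect_gt(mean(a) - mean(b), 3 * se)
})

test_that("trajectory_mean is the Monte-Carlo mean of the noise model", {
  spec <- metabolite_spec("X", "constant", params = list(base = 100),
                          cv = 0.25)
  w <- stats::setNames(rep(0, 157), 12:168)
  w["30"] <- 1   # all mass at one hour so the mean is a single value
  cfg <- generator_config(1e6, seed = 21, metabolite_specs = list(spec),
                          aabc_weights = w)
  co <- generate_cohort(cfg)
  mu <- trajectory_mean(spec, 30)
  se <- stats::sd(co$X) / sqrt(nrow(co))
  expect_lt(abs(mean(co$X) - mu), 3 * se)
})

test_that("trajectory_mean is pure, bounded to 12-168 h, shift-monotone", {
  spec <- metabolite_spec("X", "constant", params = list(base = 50),
                          cv = 0.2, shifts = c(preterm = 0.5))
  expect_equal(trajectory_mean(spec, c(12, 100, 168)), rep(50, 3))
  expect_error(trajectory_mean(spec, 11), "aabc")
  expect_error(trajectory_mean(spec, 169), "aabc")
  for (h in c(12, 60, 168)) {
    expect_gt(trajectory_mean(spec, h, covariates = list(preterm = TRUE)),
              trajectory_mean(spec, h, covariates = list(preterm = FALSE)))
  }
})

test_that("planted effects are additive and null plants change nothing", {
  cfg <- null_config(5000, seed = 4, aabc_weights = balanced_weights())
  expect_identical(generate_cohort(plant_effect(cfg, "Phe", "early", 0)),
                   generate_cohort(cfg))
  stacked <- plant_effect(plant_effect(cfg, "Phe", "early", 0.2),
                          "Phe", "early", 0.3)
  single <- plant_effect(cfg, "Phe", "early", 0.5)
  expect_identical(generate_cohort(stacked), generate_cohort(single))
  expect_error(plant_effect(cfg, "NoSuchAnalyte", "early", 1), "unknown")
})

test_that("a planted shift is recovered by downstream Cohen's d", {
  cfg <- plant_effect(null_config(40000, seed = 31,
                                  aabc_weights = balanced_weights()),
                      "Phe", "early", 0.5)
  d <- category_d(generate_cohort(cfg), "Phe")
  expect_lt(abs(d - 0.5), 0.05)
})

test_that("fp case tables follow the configured multinomial shares", {
  shares_one <- fp_model(tibble::tibble(
    disease = "A", total_fp = 10, share_early = 1, share_standard = 0,
    share_late = 0))
  cases <- generate_fp_cases(shares_one, seed = 1)
  expect_identical(nrow(cases), 10L)
  expect_true(all(cases$category == "early"))
  expect_true(all(cases$aabc >= 12 & cases$aabc <= 23))

  empty <- fp_model(tibble::tibble(
    disease = "A", total_fp = 0, share_early = 1, share_standard = 0,
    share_late = 0))
  expect_identical(nrow(generate_fp_cases(empty, seed = 1)), 0L)

  # mean early count over many seeds matches the multinomial expectation
  ctd_like <- fp_model(tibble::tibble(
    disease = "CTD", total_fp = 471, share_early = 0.093,
    share_standard = 0.809, share_late = 0.098))
  early_counts <- vapply(1:300, function(s) {
    sum(generate_fp_cases(ctd_like, seed = s)$category == "early")
  }, numeric(1))
  se <- sqrt(471 * 0.093 * (1 - 0.093) / 300)
  expect_lt(abs(mean(early_counts) - 471 * 0.093), 3 * se)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(0), "positive")
  expect_error(generator_config(10, aabc_weights = rep(-1, 157)),
               "non-negative")
  expect_error(metabolite_spec("X", "constant", params = list(base = -1)),
               "positive")
  expect_error(fp_model(tibble::tibble(disease = "A", total_fp = 5,
                                       share_early = 0.5,
                                       share_standard = 0.2,
                                       share_late = 0.2)),
               "sum to 1")
})
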