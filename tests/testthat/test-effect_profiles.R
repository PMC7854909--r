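test_that("cohen_d matches the pooled-SD formula and its symmetries", {
  expect_equal(cohen_d(c(1, 2, 3), c(2, 3, 4)), -1.0)
  x <- c(1.2, 5.3, 2.2, 4.4)
  expect_equal(cohen_d(x, x), 0)
  y <- c(2.0, 3.7, 8.1)
  expect_equal(cohen_d(x, y), -cohen_d(y, x))
  # group-size invariance: replicating every record k times leaves d
  # essentially unchanged (exact up to the n-1 variance weights, whose
  # effect vanishes with sample size) - the reason the statistic suits
  # groups of very different sizes
  set.seed(1)
  xx <- stats::rnorm(500, 1, 2); yy <- stats::rnorm(500, 0, 2)
  expect_equal(cohen_d(rep(xx, 7), rep(yy, 7)), cohen_d(xx, yy),
               tolerance = 1e-3)
  expect_equal(cohen_d(rep(xx, 9), yy), cohen_d(xx, yy), tolerance = 0.02)
  # location and positive scale invariance
  expect_equal(cohen_d(x + 7, y + 7), cohen_d(x, y), tolerance = 1e-12)
  expect_equal(cohen_d(x * 3.5, y * 3.5), cohen_d(x, y), tolerance = 1e-12)
  expect_error(cohen_d(c(1), c(1, 2)), "2 observations")
  expect_error(cohen_d(c(2, 2), c(2, 2)), "pooled")
})

test_that("cohen_d equals a brute-force oracle on random small samples", {
  set.seed(42)
  for (i in 1:100) {
    x <- stats::rnorm(sample(2:20, 1), mean = stats::runif(1, -5, 5),
                      sd = stats::runif(1, 0.1, 3))
    y <- stats::rnorm(sample(2:20, 1), mean = stats::runif(1, -5, 5),
                      sd = stats::runif(1, 0.1, 3))
    expect_equal(cohen_d(x, y), cohen_d_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("effect_matrix has the contracted shape and group counts", {
  cfg <- generator_config(6000, seed = 13,
                          metabolite_specs = default_panel()["Phe"])
  ref <- restrict_reference(apply_exclusions(generate_cohort(cfg))$records)
  em <- effect_matrix(ref, mode = "fine")
  expect_identical(dim(em$d), c(1L, 9L))
  expect_identical(rownames(em$d), "Phe")
  expect_identical(colnames(em$d), fine_bin_labels()[-1])
  expect_identical(em$reference, "12-17")
  expect_identical(sum(em$n), sum(!is.na(assign_fine_bin(ref$aabc))))
  emc <- effect_matrix(ref, mode = "category")
  expect_identical(colnames(emc$d), c("early", "late"))
  expect_identical(emc$reference, "standard")
})

test_that("planted and null category effects are recovered in the matrix", {
  cfg <- plant_effect(null_config(40000, seed = 17,
                                  aabc_weights = balanced_weights()),
                      "Phe", "early", 0.5)
  ref <- restrict_reference(apply_exclusions(generate_cohort(cfg))$records)
  em <- effect_matrix(ref, mode = "category")
  expect_lt(abs(em$d["Phe", "early"] - 0.5), 0.05)

  cfg0 <- null_config(40000, seed = 18, aabc_weights = balanced_weights())
  ref0 <- restrict_reference(apply_exclusions(generate_cohort(cfg0))$records)
  em0 <- effect_matrix(ref0, mode = "category")
  expect_lt(abs(em0$d["Phe", "early"]), 0.05)
})

test_that("marker flagging uses a strict |d| > 0.2 rule", {
  d <- matrix(c(0, 0.2, -0.2, 0.21, -0.55), nrow = 5,
              dimnames = list(paste0("M", 1:5), "early"))
  mat <- structure(list(d = d, n = c(early = 10L, standard = 10L),
                        mode = "category", reference = "standard"),
                   class = "effect_size_matrix")
  fl <- flag_markers(mat)
  expect_setequal(fl$metabolite, c("M4", "M5"))
  expect_identical(fl$direction[fl$metabolite == "M5"], "negative")
  expect_true(fl$strong[fl$metabolite == "M5"])
  zero <- mat; zero$d[] <- 0
  expect_identical(nrow(flag_markers(zero)), 0L)
})

test_that("two-cluster cut separates down- and up-trending profiles", {
  d <- rbind(down = seq(-0.1, -0.9, length.out = 9),
             up = seq(0.1, 0.9, length.out = 9))
  colnames(d) <- fine_bin_labels()[-1]
  mat <- structure(list(d = d, n = NULL, mode = "fine", reference = "12-17"),
                   class = "effect_size_matrix")
  cl <- cluster_profiles(mat)
  expect_identical(unname(cl$labels["down"]), "decreasing")
  expect_identical(unname(cl$labels["up"]), "increasing")
  # row permutation does not change labels
  mat2 <- mat
  mat2$d <- mat$d[c(2, 1), , drop = FALSE]
  cl2 <- cluster_profiles(mat2)
  expect_identical(cl$labels[names(cl2$labels)], cl2$labels)
  # identical rows degenerate to a single labeled cluster with a warning
  same <- mat
  same$d <- rbind(a = d[1, ], b = d[1, ])
  expect_warning(cls <- cluster_profiles(same), "degenerate")
  expect_identical(length(unique(cls$labels)), 1L)
})

test_that("cluster labels recover the generator's trajectory templates", {
  cfg <- generator_config(30000, seed = 5)
  ref <- restrict_reference(apply_exclusions(generate_cohort(cfg))$records)
  em <- effect_matrix(ref, mode = "fine")
  cl <- cluster_profiles(em)
  truth <- vapply(cfg$metabolite_specs, function(s) s$cluster, character(1))
  expect_gte(mean(cl$labels[names(truth)] == truth), 0.95)
})
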