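# Shared fixtures and independent oracles used across the suite.

# Hour weights with equal early/standard mass (no late tail): gives two
# large groups for effect-size recovery checks.
balanced_weights <- function(shares = c(early = 0.5, standard = 0.5,
                                        late = 0)) {
  default_aabc_weights(shares)
}

# Cohen's d between two collection categories of a cohort.
category_d <- function(records, metabolite, cat_a = "early",
                       cat_b = "standard") {
  cat_t <- assign_category(records$aabc)
  cohen_d(records[[metabolite]][cat_t == cat_a],
          records[[metabolite]][cat_t == cat_b])
}

# Independent brute-force oracle for Cohen's d: sums-of-squares form,
# no shared code with cohen_d().
cohen_d_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ssx <- sum((x - sum(x) / nx)^2)
  ssy <- sum((y - sum(y) / ny)^2)
  (sum(x) / nx - sum(y) / ny) / sqrt((ssx + ssy) / (nx + ny - 2))
}

# Independent brute-force Pearson chi-squared statistic.
chisq_oracle <- function(obs, exp) {
  total <- 0
  for (i in seq_along(obs)) total <- total + (obs[i] - exp[i])^2 / exp[i]
  total
}

# Six-record fixture exercising every exclusion rule plus one clean record.
exclusion_fixture <- function() {
  tibble::tibble(
    id = sprintf("R%d", 1:6),
    aabc = c(11L, 200L, 30L, 30L, 30L, 30L),
    ga = c(39L, 39L, 39L, 27L, 39L, 39L),
    bw = c(3000, 3000, 900, 3000, 3000, 3000),
    sex = "female",
    race_reported = "White",
    race_ethnicity = "White",
    tpn = c("no", "no", "no", "no", "unknown", "no"),
    screen = "negative",
    Phe = 50
  )
}
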