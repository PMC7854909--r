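# Observed vs expected false-positive counts per collection window,
# chi-squared enrichment tests and consistency classification against
# marker-level effect sizes.

#' Disease panel of primary screening markers
#'
#' The nine disorders analysed for false-positive enrichment, each with its
#' primary MS/MS marker and the direction of the pathological change
#' (whether disease elevates or decreases the marker). CITR pools three
#' citrulline-elevated disorders (ASA, CIT-I, CIT-II); OTCD is screened by
#' decreased citrulline and CTD by decreased free carnitine.
#'
#' @return Tibble with columns `disease`, `marker`, `direction`.
#' @export
disease_panel <- function() {
  tibble::tribble(
    ~disease, ~marker,   ~direction,
    "CTD",    "C0",      "decreased",
    "PA",     "C3",      "elevated",
    "MMA",    "C3",      "elevated",
    "IVA",    "C5",      "elevated",
    "VLCADD", "C14:1",   "elevated",
    "CITR",   "Cit",     "elevated",
    "OTCD",   "Cit",     "decreased",
    "HCY",    "Met",     "elevated",
    "PKU",    "Phe",     "elevated"
  )
}

#' Round half away from zero
#'
#' Display rounding for expected counts (base `round()` rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @return Nearest integers, ties away from zero.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Build a false-positive count table
#'
#' Applies the reference restriction (term, normal birth weight, no TPN) to
#' the case table, drops cases collected outside 12-168 h (logged), then
#' tallies cases per disease and collection category. Percentages are
#' count/total x 100 rounded to one decimal.
#'
#' @param fp_cases Tibble of false-positive cases with columns `disease`,
#'   `aabc`, `ga`, `bw`, `tpn` (as from [generate_fp_cases()]).
#' @param neg_sizes Named numeric: screen-negative counts per category
#'   (`early`, `standard`, `late`).
#' @param scheme An [aabc_scheme()].
#' @param filters A [cohort_filter_spec()] supplying the reference ranges,
#'   or `NULL` to skip the restriction.
#' @return An `fp_count_table`: tibble with per-disease observed counts,
#'   total and percentages; `neg_sizes` stored as an attribute.
#' @export
count_fp <- function(fp_cases, neg_sizes, scheme = aabc_scheme(),
                     filters = cohort_filter_spec()) {
  if (!is.null(filters)) {
    keep <- in_range(fp_cases$ga, filters$reference_ga) &
      in_range(fp_cases$bw, filters$reference_bw) &
      !is.na(fp_cases$tpn) & fp_cases$tpn == "no"
    fp_cases <- fp_cases[keep, , drop = FALSE]
  }
  cat <- assign_category(fp_cases$aabc, scheme)
  if (anyNA(cat)) {
    message(sum(is.na(cat)), " case(s) with AaBC outside 12-168 h excluded")
    fp_cases <- fp_cases[!is.na(cat), , drop = FALSE]
    cat <- cat[!is.na(cat)]
  }
  tab <- table(factor(fp_cases$disease),
               factor(cat, levels = c("early", "standard", "late")))
  out <- tibble::tibble(
    disease = rownames(tab),
    early = as.integer(tab[, "early"]),
    standard = as.integer(tab[, "standard"]),
    late = as.integer(tab[, "late"])
  )
  fp_count_table(out, neg_sizes)
}

#' Construct an fp_count_table from observed counts
#'
#' Use this to feed externally reported (printed) count tables into the
#' enrichment machinery without any case-level data.
#'
#' @param observed Tibble/data frame with columns `disease`, `early`,
#'   `standard`, `late`.
#' @inheritParams count_fp
#' @return An `fp_count_table`.
#' @export
fp_count_table <- function(observed, neg_sizes) {
  observed <- tibble::as_tibble(observed)
  needed <- c("disease", "early", "standard", "late")
  if (!all(needed %in% names(observed))) {
    stop("observed counts need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("early", "standard", "late") %in% names(neg_sizes))) {
    stop("neg_sizes must name early, standard and late", call. = FALSE)
  }
  cnt <- as.matrix(observed[, c("early", "standard", "late")])
  if (any(cnt < 0)) stop("counts must be non-negative", call. = FALSE)
  observed$total <- as.integer(rowSums(cnt))
  for (cc in c("early", "standard", "late")) {
    observed[[paste0("pct_", cc)]] <-
      ifelse(observed$total > 0,
             round(observed[[cc]] / observed$total * 100, 1), NA_real_)
  }
  structure(observed, neg_sizes = neg_sizes[c("early", "standard", "late")],
            class = c("fp_count_table", class(observed)))
}

#' Expected false-positive counts per collection window
#'
#' Under no AaBC effect, false positives should split across the windows in
#' proportion to the screen-negative group sizes:
#' `expected_i = total x neg_i / sum(neg)`. Display values are rounded to
#' the nearest integer, ties away from zero; exact values sum to the
#' observed total.
#'
#' @param table An `fp_count_table`.
#' @return Tibble with per-disease exact (`exp_*`) and display (`disp_*`)
#'   expected counts.
#' @export
expected_counts <- function(table) {
  stopifnot(inherits(table, "fp_count_table"))
  neg <- attr(table, "neg_sizes")
  if (any(neg <= 0)) stop("screen-negative sizes must all be positive",
                          call. = FALSE)
  if (any(table$total == 0)) {
    stop("zero observed total for: ",
         paste(table$disease[table$total == 0], collapse = ", "),
         "; expectation undefined", call. = FALSE)
  }
  share <- neg / sum(neg)
  out <- tibble::tibble(disease = table$disease)
  for (cc in c("early", "standard", "late")) {
    out[[paste0("exp_", cc)]] <- table$total * share[[cc]]
    out[[paste0("disp_", cc)]] <- round_half_away(table$total * share[[cc]])
  }
  out
}

#' Overall chi-squared goodness-of-fit test
#'
#' Pearson statistic of the three observed window counts against the
#' expected counts, df = 2.
#'
#' @param observed Numeric triple (early, standard, late).
#' @param expected Numeric triple of expected counts (positive).
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
gof_test <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("observed and expected lengths differ", call. = FALSE)
  }
  if (any(expected == 0)) {
    stop("expected count of zero: chi-squared test undefined", call. = FALSE)
  }
  if (any(expected < 5)) {
    warning("expected count below 5: chi-squared approximation may be poor")
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  tibble::tibble(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Per-category proportion test
#'
#' One-sample two-cell chi-squared of (obs_i, total - obs_i) against the
#' screen-negative share (pi_i, 1 - pi_i), df = 1, no continuity
#' correction. The screen-negative cohort is orders of magnitude larger
#' than any false-positive series, so its share is treated as fixed.
#'
#' @param obs Observed count in the category.
#' @param total Total false positives for the disease.
#' @param pi Screen-negative share of the category, strictly inside (0, 1).
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
category_test <- function(obs, total, pi) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (pi <= 0 || pi >= 1) {
    stop("category share must lie strictly between 0 and 1", call. = FALSE)
  }
  exp1 <- total * pi
  exp2 <- total * (1 - pi)
  stat <- (obs - exp1)^2 / exp1 + ((total - obs) - exp2)^2 / exp2
  tibble::tibble(statistic = stat, df = 1L,
                 p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Full enrichment analysis of a count table
#'
#' Per disease: exact and display expected counts, the overall df = 2
#' goodness-of-fit test, per-category proportion tests with significance
#' stars, and the excess/deficit direction per category.
#'
#' @param table An `fp_count_table`.
#' @return An `enrichment_result` tibble (one row per disease).
#' @export
enrichment <- function(table) {
  stopifnot(inherits(table, "fp_count_table"))
  neg <- attr(table, "neg_sizes")
  share <- neg / sum(neg)
  exp_tab <- expected_counts(table)
  out <- dplyr::left_join(tibble::as_tibble(table), exp_tab, by = "disease")
  gof <- mapply(function(e, s, l, ee, es, el) {
    g <- gof_test(c(e, s, l), c(ee, es, el))
    c(g$statistic, g$p)
  }, out$early, out$standard, out$late,
     out$exp_early, out$exp_standard, out$exp_late)
  out$chisq_overall <- gof[1, ]
  out$p_overall <- gof[2, ]
  for (cc in c("early", "standard", "late")) {
    p_cc <- mapply(function(o, t) category_test(o, t, share[[cc]])$p,
                   out[[cc]], out$total)
    out[[paste0("p_", cc)]] <- p_cc
    out[[paste0("stars_", cc)]] <- significance_stars(p_cc)
    diff <- out[[cc]] - out[[paste0("exp_", cc)]]
    out[[paste0("direction_", cc)]] <-
      ifelse(diff > 0, "excess", ifelse(diff < 0, "deficit", "none"))
  }
  structure(out, neg_sizes = neg,
            class = c("enrichment_result", class(tibble::tibble())))
}

#' Classify marker/false-positive consistency for one disease and window
#'
#' A marker shifted at a given collection window predicts a same-direction
#' shift in false positives when disease elevates the marker, and an
#' opposite-direction shift when disease decreases it (a lower
#' physiological level moves healthy infants toward a "decreased" cutoff
#' and away from an "elevated" one). The call is:
#' \itemize{
#'   \item `indeterminate` when |d| <= 0.2 (marker not flagged), when the
#'     enrichment is not significant, or when observed equals expected;
#'   \item `consistent` when the observed-minus-expected sign matches the
#'     predicted sign and the enrichment is significant;
#'   \item `inconsistent` when significant with the opposite sign.
#' }
#' Significance defaults to the overall df = 2 goodness-of-fit test
#' (`p_source = "overall"`); the per-category proportion test is available
#' via `p_source = "category"`.
#'
#' @param d Cohen's d of the marker in the window (screen-negatives,
#'   window vs standard).
#' @param direction `"elevated"` or `"decreased"`: pathological marker
#'   change of the disease.
#' @param observed,expected Observed and (exact) expected false-positive
#'   counts in the window.
#' @param p_overall,p_category P-values from [gof_test()] and
#'   [category_test()].
#' @param alpha Significance level.
#' @param p_source Which p-value gates the call.
#' @param flag_threshold Absolute-d flagging threshold (strict).
#' @return Tibble with `call`, `predicted_shift`, `observed_shift`, `d`,
#'   `p_used`.
#' @export
classify_consistency <- function(d, direction, observed, expected,
                                 p_overall, p_category = NA_real_,
                                 alpha = 0.05,
                                 p_source = c("overall", "category"),
                                 flag_threshold = 0.2) {
  p_source <- match.arg(p_source)
  direction <- match.arg(direction, c("elevated", "decreased"))
  p_used <- if (p_source == "overall") p_overall else p_category
  predicted <- sign(d) * if (direction == "elevated") 1 else -1
  observed_shift <- sign(observed - expected)
  call <- if (is.na(d) || abs(d) <= flag_threshold) {
    "indeterminate"
  } else if (is.na(p_used) || p_used >= alpha || observed_shift == 0) {
    "indeterminate"
  } else if (observed_shift == predicted) {
    "consistent"
  } else {
    "inconsistent"
  }
  tibble::tibble(call = call, predicted_shift = predicted,
                 observed_shift = observed_shift, d = d, p_used = p_used)
}

#' Table of consistency calls for every disease and window
#'
#' Joins marker effect sizes to the enrichment results and classifies every
#' (disease, window) pair.
#'
#' @param enr An [enrichment()] result.
#' @param effects Tibble with columns `disease`, `d_early`, `d_late`
#'   (marker Cohen's d for the early and late windows vs standard).
#' @param panel A [disease_panel()]-shaped tibble (`disease`, `marker`,
#'   `direction`).
#' @inheritParams classify_consistency
#' @return Tibble with one row per disease x window (`early`, `late`) and
#'   the consistency `call`.
#' @export
consistency_calls <- function(enr, effects, panel = disease_panel(),
                              alpha = 0.05,
                              p_source = c("overall", "category"),
                              flag_threshold = 0.2) {
  p_source <- match.arg(p_source)
  dat <- dplyr::left_join(tibble::as_tibble(enr), effects, by = "disease")
  dat <- dplyr::left_join(dat, panel, by = "disease")
  rows <- list()
  for (i in seq_len(nrow(dat))) {
    for (cc in c("early", "late")) {
      cl <- classify_consistency(
        d = dat[[paste0("d_", cc)]][i],
        direction = dat$direction[i],
        observed = dat[[cc]][i],
        expected = dat[[paste0("exp_", cc)]][i],
        p_overall = dat$p_overall[i],
        p_category = dat[[paste0("p_", cc)]][i],
        alpha = alpha, p_source = p_source,
        flag_threshold = flag_threshold
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        disease = dat$disease[i], marker = dat$marker[i],
        direction = dat$direction[i], category = cc, cl
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Assemble a screening-performance summary table
#'
#' One row per disease: marker and direction, early/late marker effect
#' sizes, observed counts with percentages, display expected counts,
#' per-category significance stars and early/late consistency calls.
#'
#' @inheritParams consistency_calls
#' @return Tibble shaped like a screening-performance report table.
#' @export
performance_table <- function(enr, effects, panel = disease_panel(),
                              alpha = 0.05,
                              p_source = c("overall", "category")) {
  p_source <- match.arg(p_source)
  calls <- consistency_calls(enr, effects, panel, alpha = alpha,
                             p_source = p_source)
  calls_w <- tibble::tibble(
    disease = unique(calls$disease),
    call_early = calls$call[calls$category == "early"][
      match(unique(calls$disease), calls$disease[calls$category == "early"])],
    call_late = calls$call[calls$category == "late"][
      match(unique(calls$disease), calls$disease[calls$category == "late"])]
  )
  dat <- dplyr::left_join(tibble::as_tibble(enr), effects, by = "disease")
  dat <- dplyr::left_join(dat, panel, by = "disease")
  dat <- dplyr::left_join(dat, calls_w, by = "disease")
  fmt <- function(o, p, e, s) sprintf("%d (%.1f%%) E: %d%s", o, p, e, s)
  tibble::tibble(
    disease = dat$disease, marker = dat$marker, direction = dat$direction,
    d_early = dat$d_early, d_late = dat$d_late,
    early = fmt(dat$early, dat$pct_early, dat$disp_early, dat$stars_early),
    standard = fmt(dat$standard, dat$pct_standard, dat$disp_standard,
                   dat$stars_standard),
    late = fmt(dat$late, dat$pct_late, dat$disp_late, dat$stars_late),
    p_overall = dat$p_overall,
    call_early = dat$call_early, call_late = dat$call_late
  )
}
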