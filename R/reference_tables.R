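# Packaged reference tables: published per-window false-positive counts,
# marker effect sizes, screen-negative group sizes and cohort totals from a
# state screening program, shipped so the enrichment machinery runs with
# zero simulation.

#' Load the packaged screening-performance reference tables
#'
#' Returns the published per-disease false-positive counts per collection
#' window, the marker effect sizes (early and late vs standard), the
#' screen-negative group sizes (90,060 early / 305,674 standard / 19,135
#' late) and the cohort totals at each filtering stage.
#'
#' @return List with elements:
#'   \describe{
#'     \item{counts}{`fp_count_table` of observed false positives}
#'     \item{effects}{tibble `disease`, `d_early`, `d_late`}
#'     \item{panel}{tibble `disease`, `marker`, `direction`}
#'     \item{neg_sizes}{named numeric, screen-negative counts per window}
#'     \item{totals}{named numeric: `screened`, `after_exclusions`,
#'       `reference`}
#'   }
#' @export
load_reference_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "nbstiming",
                                 mustWork = TRUE)
  raw <- readr::read_tsv(ext("table1_fp_counts.tsv"),
                         col_types = "cccddiii", progress = FALSE)
  neg <- readr::read_tsv(ext("screen_negative_sizes.tsv"), col_types = "cd",
                         progress = FALSE)
  tot <- readr::read_tsv(ext("cohort_totals.tsv"), col_types = "cd",
                         progress = FALSE)
  neg_sizes <- stats::setNames(neg$n, neg$category)
  list(
    counts = fp_count_table(raw[, c("disease", "early", "standard", "late")],
                            neg_sizes),
    effects = raw[, c("disease", "d_early", "d_late")],
    panel = raw[, c("disease", "marker", "direction")],
    neg_sizes = neg_sizes,
    totals = stats::setNames(tot$n, tot$quantity)
  )
}

#' Percentage share, rounded to one decimal
#'
#' @param n Subset size.
#' @param total Whole-group size.
#' @return `n / total * 100` rounded to one decimal.
#' @export
pct_share <- function(n, total) round(n / total * 100, 1)
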