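# Cohort data model: AaBC binning schemes, exclusion rules, reference
# restriction and race/ethnicity reclassification.

#' Reserved (non-metabolite) column names of a newborn record table
#'
#' @return Character vector of covariate column names.
#' @export
record_covariate_columns <- function() {
  c("id", "aabc", "ga", "bw", "sex", "race_reported", "race_ethnicity",
    "tpn", "screen")
}

#' Metabolite columns of a record table
#'
#' Every column that is not a clinical covariate is treated as an analyte
#' concentration.
#'
#' @param records A newborn record tibble.
#' @return Character vector of analyte column names.
#' @export
metabolite_names <- function(records) {
  setdiff(names(records), record_covariate_columns())
}

#' Age-at-blood-collection binning scheme
#'
#' Two binning systems used throughout: ten fine 6-hour windows covering
#' 12-72 h (the last window, 66-72 h, is 7 hours wide), and three coarse
#' collection categories: early (12-23 h), standard (24-48 h) and
#' late (49-168 h). Fine bin 0 (12-17 h) and the standard category are the
#' respective reference groups.
#'
#' @return An object of class `aabc_scheme`.
#' @export
aabc_scheme <- function() {
  structure(
    list(
      fine_start = c(12L, 18L, 24L, 30L, 36L, 42L, 48L, 54L, 60L, 66L),
      fine_end   = c(17L, 23L, 29L, 35L, 41L, 47L, 53L, 59L, 65L, 72L),
      categories = list(early = c(12L, 23L), standard = c(24L, 48L),
                        late = c(49L, 168L)),
      reference_fine = 0L,
      reference_category = "standard"
    ),
    class = "aabc_scheme"
  )
}

#' Labels of the fine 6-hour AaBC bins
#'
#' @param scheme An [aabc_scheme()].
#' @return Character vector like `"12-17"`, indexed by bin 0..9.
#' @export
fine_bin_labels <- function(scheme = aabc_scheme()) {
  paste0(scheme$fine_start, "-", scheme$fine_end)
}

#' Assign the fine 6-hour AaBC bin
#'
#' Hours outside 12-72 (including all late collections) fall in no fine bin
#' and map to `NA`. Bin indices are 0-based: bin 0 is the 12-17 h reference.
#'
#' @param aabc Integer hours since birth (vectorized).
#' @param scheme An [aabc_scheme()].
#' @return Integer bin index 0-9, or `NA` outside 12-72 h.
#' @export
assign_fine_bin <- function(aabc, scheme = aabc_scheme()) {
  stopifnot(is.numeric(aabc))
  idx <- findInterval(aabc, c(scheme$fine_start, scheme$fine_end[10] + 1L)) - 1L
  idx[is.na(aabc) | aabc < scheme$fine_start[1] | aabc > scheme$fine_end[10]] <- NA_integer_
  as.integer(idx)
}

#' Assign the coarse collection category
#'
#' @param aabc Integer hours since birth (vectorized).
#' @param scheme An [aabc_scheme()].
#' @return Character: `"early"`, `"standard"` or `"late"`; `NA` outside
#'   12-168 h.
#' @export
assign_category <- function(aabc, scheme = aabc_scheme()) {
  stopifnot(is.numeric(aabc))
  out <- rep(NA_character_, length(aabc))
  for (cat in names(scheme$categories)) {
    rng <- scheme$categories[[cat]]
    out[!is.na(aabc) & aabc >= rng[1] & aabc <= rng[2]] <- cat
  }
  out
}

#' Cohort exclusion and reference-restriction rules
#'
#' Population-level exclusions keep records with blood collection between 12
#' and 168 h, birth weight 1,000-5,000 g, gestational age 28-42 weeks and
#' (when enabled) known, negative TPN status. The reference restriction used
#' for effect-size analysis further narrows to term infants (37-41 weeks)
#' with normal birth weight (2,500-4,000 g) and no TPN. All bounds are
#' inclusive on integer hours/grams/weeks.
#'
#' @param aabc_range,bw_range,ga_range Inclusive `[lo, hi]` retention ranges.
#' @param reference_ga,reference_bw Inclusive ranges for the reference subset.
#' @param tpn_exclude TPN values dropped by the exclusion rule.
#' @return An object of class `cohort_filter_spec`.
#' @export
cohort_filter_spec <- function(aabc_range = c(12L, 168L),
                               bw_range = c(1000, 5000),
                               ga_range = c(28L, 42L),
                               reference_ga = c(37L, 41L),
                               reference_bw = c(2500, 4000),
                               tpn_exclude = c("yes", "unknown")) {
  for (rng in list(aabc_range, bw_range, ga_range, reference_ga, reference_bw)) {
    if (length(rng) != 2L || any(is.na(rng)) || rng[1] > rng[2]) {
      stop("each range must be a finite [lo, hi] pair with lo <= hi",
           call. = FALSE)
    }
  }
  structure(
    list(aabc_range = aabc_range, bw_range = bw_range, ga_range = ga_range,
         reference_ga = reference_ga, reference_bw = reference_bw,
         tpn_exclude = tpn_exclude),
    class = "cohort_filter_spec"
  )
}

in_range <- function(x, rng) !is.na(x) & x >= rng[1] & x <= rng[2]

#' Apply population-level exclusion rules
#'
#' Drops records violating any enabled rule and tallies exclusions with
#' first-matching-rule attribution in the fixed order aabc, bw, ga, tpn.
#' Unknown (`NA`) AaBC, birth weight or gestational age, and TPN values in
#' `spec$tpn_exclude`, are dropped under their rule.
#'
#' @param records Newborn record tibble.
#' @param spec A [cohort_filter_spec()].
#' @return List with elements `records` (retained rows) and `tally`
#'   (named integer counts per rule).
#' @export
apply_exclusions <- function(records, spec = cohort_filter_spec()) {
  bad_aabc <- !in_range(records$aabc, spec$aabc_range)
  bad_bw   <- !in_range(records$bw, spec$bw_range)
  bad_ga   <- !in_range(records$ga, spec$ga_range)
  bad_tpn  <- is.na(records$tpn) | records$tpn %in% spec$tpn_exclude

  rule <- rep(NA_character_, nrow(records))
  rule[bad_tpn]  <- "tpn"
  rule[bad_ga]   <- "ga"
  rule[bad_bw]   <- "bw"
  rule[bad_aabc] <- "aabc"   # assigned last: first-match priority

  tally <- vapply(c("aabc", "bw", "ga", "tpn"),
                  function(r) sum(rule == r, na.rm = TRUE), integer(1))
  list(records = records[is.na(rule), , drop = FALSE], tally = tally)
}

#' Restrict to the reference subset
#'
#' Keeps term infants (GA 37-41 weeks) with birth weight 2,500-4,000 g and
#' TPN recorded as `"no"`; boundaries inclusive. This is the subset used for
#' effect-size and false-positive analyses to control for GA, BW and TPN.
#'
#' @inheritParams apply_exclusions
#' @return The restricted record tibble.
#' @export
restrict_reference <- function(records, spec = cohort_filter_spec()) {
  keep <- in_range(records$ga, spec$reference_ga) &
    in_range(records$bw, spec$reference_bw) &
    !is.na(records$tpn) & records$tpn == "no"
  records[keep, , drop = FALSE]
}

#' Classify reported race/ethnicity sets
#'
#' Newborns reported with more than one race/ethnicity are classified by a
#' priority cascade: (a) Hispanic if Hispanic is reported with any other
#' category; (b) Black if Black is reported with any other category except
#' Hispanic; (c) Asian if Asian is reported with any other category except
#' Hispanic and Black; (d) White only if White is the sole reported
#' category. Everything else, including empty or unknown reports, is
#' Other/Unknown.
#'
#' @param reported Either a character vector of `"|"`-separated category
#'   sets (e.g. `"Hispanic|White"`) or a list of character vectors. Known
#'   categories are Asian, Black, Hispanic, White and other.
#' @return Character vector over
#'   `{Hispanic, Black, Asian, White, Other/Unknown}`.
#' @export
classify_race_ethnicity <- function(reported) {
  if (!is.list(reported)) {
    reported <- strsplit(ifelse(is.na(reported), "", reported), "|", fixed = TRUE)
  }
  vapply(reported, function(set) {
    set <- setdiff(unique(set), "")
    if ("Hispanic" %in% set) return("Hispanic")
    if ("Black" %in% set) return("Black")
    if ("Asian" %in% set) return("Asian")
    if (identical(set, "White")) return("White")
    "Other/Unknown"
  }, character(1))
}
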