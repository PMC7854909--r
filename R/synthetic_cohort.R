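# Synthetic newborn-screening cohort generator: analyte trajectories over
# age at blood collection, covariate effects, multiplicative lognormal
# noise, planted category effects and false-positive case tables.

AABC_MIN <- 12L
AABC_MAX <- 168L

#' Specification of one synthetic analyte
#'
#' The mean concentration is a smooth function of age at blood collection
#' (AaBC) built from one of four parametric templates:
#' \describe{
#'   \item{decreasing}{exponential decay to a plateau:
#'     `base + amp * exp(-rate * (t - 12))`}
#'   \item{increasing}{saturating rise:
#'     `base + amp * (1 - exp(-rate * (t - 12)))`}
#'   \item{dip_then_rise}{fast decay plus slow rise:
#'     `base + amp_dec * exp(-rate_dec * (t-12)) + amp_inc * (1 - exp(-rate_inc * (t-12)))`}
#'   \item{constant}{`base` at every hour}
#' }
#' Noise is multiplicative lognormal with unit mean and coefficient of
#' variation `cv` (keeps concentrations positive; screening analytes are
#' right-skewed). Covariate effects are additive offsets in units of the
#' analyte's log-scale SD, applied multiplicatively as
#' `exp(offset * sigma_log)`.
#'
#' @param name Analyte identifier, e.g. `"Phe"`, `"C0"`, `"C14:1"`.
#' @param shape Trajectory template tag.
#' @param params Named list of template parameters (see above).
#' @param cv Coefficient of variation of the lognormal noise factor.
#' @param shifts Named numeric covariate offsets in log-SD units; recognised
#'   names: `preterm`, `male`, `tpn`, and race categories `Asian`, `Black`,
#'   `Hispanic`, `White`, `Other/Unknown`.
#' @param cluster Optional ground-truth cluster tag (`"decreasing"` or
#'   `"increasing"`) used by recovery tests; inferred from `shape` when
#'   missing.
#' @return An object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name,
                            shape = c("decreasing", "increasing",
                                      "dip_then_rise", "constant"),
                            params = list(),
                            cv = 0.25,
                            shifts = NULL,
                            cluster = NULL) {
  shape <- match.arg(shape)
  defaults <- switch(shape,
    decreasing    = list(base = 100, amp = 35, rate = 0.04),
    increasing    = list(base = 100, amp = 35, rate = 0.04),
    dip_then_rise = list(base = 100, amp_dec = 25, rate_dec = 0.12,
                         amp_inc = 40, rate_inc = 0.02),
    constant      = list(base = 100)
  )
  params <- utils::modifyList(defaults, as.list(params))
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  spec <- structure(
    list(name = name, shape = shape, params = params, cv = cv,
         shifts = shifts %||% numeric(0),
         planted = c(early = 0, standard = 0, late = 0),
         cluster = cluster %||%
           if (shape == "decreasing") "decreasing" else "increasing"),
    class = "metabolite_spec"
  )
  if (any(base_trajectory(spec, AABC_MIN:AABC_MAX) <= 0)) {
    stop("trajectory for '", name, "' is not strictly positive on 12-168 h",
         call. = FALSE)
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free template mean, before covariate effects and planted shifts.
base_trajectory <- function(spec, t) {
  p <- spec$params
  d <- t - AABC_MIN
  switch(spec$shape,
    decreasing    = p$base + p$amp * exp(-p$rate * d),
    increasing    = p$base + p$amp * (1 - exp(-p$rate * d)),
    dip_then_rise = p$base + p$amp_dec * exp(-p$rate_dec * d) +
                    p$amp_inc * (1 - exp(-p$rate_inc * d)),
    constant      = rep(p$base, length(t))
  )
}

# sigma of log(noise factor) for a unit-mean lognormal with coefficient of
# variation cv.
sigma_log <- function(cv) sqrt(log(1 + cv^2))

# SD of the unplanted concentration at hour t (noise only, no covariates):
# the unit used by planted category effects.
noise_sd <- function(spec, t) base_trajectory(spec, t) * spec$cv

#' Noise-free conditional mean concentration
#'
#' Pure function returning the expected concentration for one analyte at
#' given AaBC hours and covariates: template trajectory, times the
#' multiplicative covariate factor `exp(offset * sigma_log)`, plus any
#' planted category effect (in units of the analyte's per-hour noise SD).
#'
#' @param spec A [metabolite_spec()].
#' @param aabc Hours since birth, each within 12-168.
#' @param covariates Optional list/data frame with any of `preterm`
#'   (logical), `sex` (`"male"`/`"female"`/`"unknown"`), `race_ethnicity`
#'   (classified category), `tpn` (`"yes"`/`"no"`/`"unknown"`).
#' @return Numeric vector of conditional means.
#' @export
trajectory_mean <- function(spec, aabc, covariates = NULL) {
  if (any(is.na(aabc)) || any(aabc < AABC_MIN | aabc > AABC_MAX)) {
    stop("aabc must lie within [", AABC_MIN, ", ", AABC_MAX, "] hours",
         call. = FALSE)
  }
  m <- base_trajectory(spec, aabc)
  off <- 0
  s <- spec$shifts
  getshift <- function(nm) if (!is.na(s[nm])) unname(s[nm]) else 0
  if (!is.null(covariates)) {
    if (!is.null(covariates$preterm))
      off <- off + getshift("preterm") * as.numeric(covariates$preterm)
    if (!is.null(covariates$sex))
      off <- off + getshift("male") * as.numeric(covariates$sex == "male")
    if (!is.null(covariates$tpn))
      off <- off + getshift("tpn") * as.numeric(covariates$tpn == "yes")
    if (!is.null(covariates$race_ethnicity)) {
      race <- as.character(covariates$race_ethnicity)
      rs <- ifelse(is.na(s[race]), 0, s[race])
      off <- off + unname(rs)
    }
  }
  m <- m * exp(off * sigma_log(spec$cv))
  if (any(spec$planted != 0)) {
    cat_t <- assign_category(aabc)
    delta <- ifelse(is.na(cat_t), 0, spec$planted[cat_t])
    m <- m + delta * noise_sd(spec, aabc)
  }
  m
}

#' Covariate-generating model for synthetic cohorts
#'
#' Defaults emulate a large state screening program: about 5 percent preterm
#' births, birth weight rising with gestational age around 3.4 kg at term,
#' a near-even sex split, a race/ethnicity mix dominated by Hispanic and
#' White reports with occasional multi-category reports, and rare TPN.
#'
#' @param ga_probs Named probabilities over gestational weeks 28-42.
#' @param bw_mean_term,bw_sd Birth-weight mean at 39 weeks and SD (grams).
#' @param bw_slope Grams of birth weight per gestational week.
#' @param sex_probs,tpn_probs Named probability vectors.
#' @param race_probs Named probabilities over primary race/ethnicity report.
#' @param multi_race_prob Probability that a second category is co-reported.
#' @return An object of class `covariate_model`.
#' @export
covariate_model <- function(ga_probs = NULL,
                            bw_mean_term = 3400, bw_sd = 420, bw_slope = 130,
                            sex_probs = c(male = 0.515, female = 0.485),
                            race_probs = c(Hispanic = 0.50, White = 0.26,
                                           Asian = 0.157, Black = 0.067,
                                           other = 0.016),
                            multi_race_prob = 0.15,
                            tpn_probs = c(no = 0.992, yes = 0.006,
                                          unknown = 0.002)) {
  if (is.null(ga_probs)) {
    w <- c(0.2, 0.2, 0.3, 0.4, 0.5, 0.6, 0.9, 1.6, 3.0, 8.0, 18.0, 30.0,
           26.0, 9.0, 1.3)
    ga_probs <- stats::setNames(w / sum(w), 28:42)
  }
  for (p in list(ga_probs, sex_probs, race_probs, tpn_probs)) {
    if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  }
  structure(
    list(ga_probs = ga_probs / sum(ga_probs),
         bw_mean_term = bw_mean_term, bw_sd = bw_sd, bw_slope = bw_slope,
         sex_probs = sex_probs / sum(sex_probs),
         race_probs = race_probs / sum(race_probs),
         multi_race_prob = multi_race_prob,
         tpn_probs = tpn_probs / sum(tpn_probs)),
    class = "covariate_model"
  )
}

#' Default AaBC hour distribution
#'
#' Category masses follow the screening-program shares: 21.7 percent early
#' (12-23 h), 73.7 percent standard (24-48 h) and 4.6 percent late
#' (49-168 h), with collection concentrated around 24-40 h and a geometric
#' tail over the late window.
#'
#' @param shares Named category masses (early, standard, late); renormalised.
#' @return Named numeric weights over hours 12-168 summing to 1.
#' @export
default_aabc_weights <- function(shares = c(early = 0.217, standard = 0.737,
                                            late = 0.046)) {
  shares <- shares / sum(shares)
  hours <- AABC_MIN:AABC_MAX
  w <- numeric(length(hours))
  names(w) <- hours
  early_h <- 12:23
  w[as.character(early_h)] <- seq(0.5, 1.5, length.out = length(early_h))
  std_h <- 24:48
  w[as.character(std_h)] <- stats::dnorm(std_h, mean = 30, sd = 8)
  late_h <- 49:168
  w[as.character(late_h)] <- 0.93^(late_h - 49)
  for (cat in names(shares)) {
    rng <- aabc_scheme()$categories[[cat]]
    sel <- as.character(rng[1]:rng[2])
    w[sel] <- w[sel] / sum(w[sel]) * shares[[cat]]
  }
  w
}

#' Default 41-analyte panel
#'
#' The standard MS/MS screening panel: 11 amino acids and 30
#' acylcarnitines. Twenty analytes follow decreasing templates and 21
#' increasing ones (leucine-isoleucine dips over the first day before
#' rising), mirroring the two trajectory clusters seen in population
#' screening data. Scales are in abstract concentration units with
#' micromol/L semantics: amino acids of order 100, acylcarnitines of order
#' 0.1-25.
#'
#' @param cv Noise coefficient of variation applied to every analyte.
#' @return Named list of [metabolite_spec()]s, length 41.
#' @export
default_panel <- function(cv = 0.25) {
  dec <- c("Phe", "Met", "Tyr", "Ala", "Gly", "Pro", "Orn", "Arg",
           "C0", "C3", "C3DC", "C4", "C4OH", "C5", "C5:1", "C5OH", "C5DC",
           "C6", "C6DC", "C16OH")
  inc <- c("Cit", "Val", "C2", "C8", "C8:1", "C10", "C10:1", "C10:2",
           "C12", "C12:1", "C14", "C14:1", "C14OH", "C16", "C16:1",
           "C18", "C18:1", "C18:2", "C18OH", "C18:1OH")
  scale_of <- function(nm) {
    if (nm %in% c("Phe", "Met", "Tyr", "Ala", "Gly", "Pro", "Orn", "Arg",
                  "Cit", "Val")) {
      c(Ala = 250, Gly = 350, Pro = 150, Val = 120, Phe = 55, Tyr = 75,
        Met = 22, Orn = 95, Arg = 12, Cit = 13)[[nm]]
    } else if (nm %in% c("C0", "C2")) c(C0 = 25, C2 = 18)[[nm]]
    else 0.6
  }
  shifts_for <- function(nm) {
    # qualitative covariate separations: preterm/TPN raise most analytes,
    # C0 higher in males and Asian infants, C18:1 lower in females.
    s <- c(preterm = 0.3, tpn = 0.8)
    if (nm == "C0") s <- c(s, male = 0.2, Asian = 0.25, Black = -0.15)
    if (nm == "C18:1") s <- c(s, male = 0.15)
    s
  }
  specs <- list()
  for (nm in dec) {
    sc <- scale_of(nm)
    specs[[nm]] <- metabolite_spec(nm, "decreasing",
      params = list(base = sc, amp = 0.35 * sc, rate = 0.04),
      cv = cv, shifts = shifts_for(nm))
  }
  for (nm in inc) {
    sc <- scale_of(nm)
    specs[[nm]] <- metabolite_spec(nm, "increasing",
      params = list(base = sc, amp = 0.35 * sc, rate = 0.04),
      cv = cv, shifts = shifts_for(nm))
  }
  specs[["Leu-Ile"]] <- metabolite_spec("Leu-Ile", "dip_then_rise",
    params = list(base = 110, amp_dec = 28, rate_dec = 0.12,
                  amp_inc = 48, rate_inc = 0.02),
    cv = cv, shifts = shifts_for("Leu-Ile"), cluster = "increasing")
  specs
}

#' False-positive case model
#'
#' Per disease: a total number of false-positive screens and the
#' probabilities that a case arises in the early, standard or late
#' collection window.
#'
#' @param diseases Tibble/data frame with columns `disease`, `total_fp`,
#'   `share_early`, `share_standard`, `share_late` (shares sum to 1 per row).
#' @return An object of class `fp_model`.
#' @export
fp_model <- function(diseases) {
  diseases <- tibble::as_tibble(diseases)
  needed <- c("disease", "total_fp", "share_early", "share_standard",
              "share_late")
  if (!all(needed %in% names(diseases))) {
    stop("fp model needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  sums <- diseases$share_early + diseases$share_standard + diseases$share_late
  shares <- as.matrix(diseases[, c("share_early", "share_standard",
                                   "share_late")])
  if (any(shares < 0) || any(abs(sums - 1) > 1e-8)) {
    stop("category shares must be non-negative and sum to 1 per disease",
         call. = FALSE)
  }
  if (any(diseases$total_fp < 0)) stop("total_fp must be >= 0", call. = FALSE)
  structure(list(diseases = diseases), class = "fp_model")
}

#' Generator configuration for a synthetic cohort
#'
#' @param n_newborns Number of records to generate (> 0).
#' @param seed Integer seed; identical config + seed gives an identical
#'   cohort. The global seed is expanded into independent sub-seeds for the
#'   cohort and false-positive streams.
#' @param aabc_weights Named weights over hours 12-168 (non-negative,
#'   normalised to sum to 1).
#' @param metabolite_specs Named list of [metabolite_spec()]s.
#' @param covariates A [covariate_model()].
#' @param fp A [fp_model()] or `NULL`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_newborns,
                             seed = 1L,
                             aabc_weights = default_aabc_weights(),
                             metabolite_specs = default_panel(),
                             covariates = covariate_model(),
                             fp = NULL) {
  if (length(n_newborns) != 1L || is.na(n_newborns) || n_newborns <= 0) {
    stop("n_newborns must be a positive count", call. = FALSE)
  }
  if (any(aabc_weights < 0) || sum(aabc_weights) <= 0) {
    stop("aabc weights must be non-negative with positive sum", call. = FALSE)
  }
  if (length(aabc_weights) != AABC_MAX - AABC_MIN + 1L) {
    stop("aabc weights must cover every hour 12-168", call. = FALSE)
  }
  nm <- vapply(metabolite_specs, function(s) s$name, character(1))
  names(metabolite_specs) <- nm
  structure(
    list(n_newborns = as.integer(n_newborns), seed = as.integer(seed),
         aabc_weights = aabc_weights / sum(aabc_weights),
         metabolite_specs = metabolite_specs,
         covariates = covariates, fp = fp),
    class = "generator_config"
  )
}

#' Null generator configuration
#'
#' Flat (constant) trajectories for every analyte: no AaBC signal, so any
#' downstream effect size reflects sampling noise only. Used for null
#' calibration and planted-effect recovery.
#'
#' @param n_newborns,seed As in [generator_config()].
#' @param metabolites Analyte names for the flat panel.
#' @param cv Noise coefficient of variation.
#' @param aabc_weights Optional hour weights (default program mix).
#' @return A `generator_config`.
#' @export
null_config <- function(n_newborns, seed = 1L, metabolites = "Phe",
                        cv = 0.25, aabc_weights = default_aabc_weights()) {
  specs <- lapply(metabolites, function(nm) {
    metabolite_spec(nm, "constant", params = list(base = 100), cv = cv,
                    shifts = c(preterm = 0))
  })
  names(specs) <- metabolites
  generator_config(n_newborns, seed = seed, aabc_weights = aabc_weights,
                   metabolite_specs = specs)
}

#' Plant a uniform category effect on one analyte
#'
#' Returns a config whose conditional mean for `metabolite` is shifted by
#' `delta_sd` noise-SD units at every hour of the given collection window,
#' leaving other hours unchanged. The shift is an additive location shift
#' applied after noise, so group variance is unchanged and repeated plants
#' add exactly: downstream Cohen's d of the planted window against an
#' unshifted one recovers `delta_sd` (for flat trajectories, exactly in
#' expectation).
#'
#' @param config A [generator_config()].
#' @param metabolite Analyte name present in the config.
#' @param category `"early"`, `"standard"` or `"late"`.
#' @param delta_sd Shift in noise-SD units.
#' @return The modified `generator_config`.
#' @export
plant_effect <- function(config, metabolite, category, delta_sd) {
  category <- match.arg(category, c("early", "standard", "late"))
  if (!metabolite %in% names(config$metabolite_specs)) {
    stop("unknown metabolite: ", metabolite, call. = FALSE)
  }
  config$metabolite_specs[[metabolite]]$planted[category] <-
    config$metabolite_specs[[metabolite]]$planted[category] + delta_sd
  config
}

# Deterministic sub-seed per stream, kept within 32-bit range.
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1000003) %% 2147483647)
}

#' Generate a synthetic screen-negative cohort
#'
#' Draws `n_newborns` records: AaBC hour from the configured weights,
#' covariates from the covariate model, and each analyte as
#' `trajectory(aabc) x covariate factor x lognormal noise` plus any planted
#' category shift. All records are screen-negative.
#'
#' @param config A [generator_config()].
#' @return Tibble with one row per infant: covariate columns (see
#'   [record_covariate_columns()]) and one column per analyte.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(sub_seed(config$seed, 0L))
  n <- config$n_newborns
  hours <- AABC_MIN:AABC_MAX
  aabc <- sample(hours, n, replace = TRUE, prob = config$aabc_weights)

  cm <- config$covariates
  ga <- sample(as.integer(names(cm$ga_probs)), n, replace = TRUE,
               prob = cm$ga_probs)
  bw <- stats::rnorm(n, mean = cm$bw_mean_term + cm$bw_slope * (ga - 39),
                     sd = cm$bw_sd)
  bw <- round(pmax(bw, 300))
  sex <- sample(names(cm$sex_probs), n, replace = TRUE, prob = cm$sex_probs)
  primary <- sample(names(cm$race_probs), n, replace = TRUE,
                    prob = cm$race_probs)
  second <- sample(names(cm$race_probs), n, replace = TRUE,
                   prob = cm$race_probs)
  multi <- stats::runif(n) < cm$multi_race_prob & second != primary
  race_reported <- ifelse(multi, paste(primary, second, sep = "|"), primary)
  tpn <- sample(names(cm$tpn_probs), n, replace = TRUE, prob = cm$tpn_probs)

  rec <- tibble::tibble(
    id = sprintf("NB%07d", seq_len(n)),
    aabc = as.integer(aabc), ga = as.integer(ga), bw = as.numeric(bw),
    sex = sex, race_reported = race_reported,
    race_ethnicity = classify_race_ethnicity(race_reported),
    tpn = tpn, screen = "negative"
  )

  covars <- list(preterm = rec$ga <= 36L, sex = rec$sex,
                 race_ethnicity = rec$race_ethnicity, tpn = rec$tpn)
  cat_t <- assign_category(rec$aabc)
  for (spec in config$metabolite_specs) {
    mu <- base_trajectory(spec, rec$aabc)
    s <- spec$shifts
    getshift <- function(nmv) ifelse(is.na(s[nmv]), 0, s[nmv])
    off <- getshift("preterm") * as.numeric(covars$preterm) +
      getshift("male") * as.numeric(covars$sex == "male") +
      getshift("tpn") * as.numeric(covars$tpn == "yes") +
      unname(getshift(covars$race_ethnicity))
    sig <- sigma_log(spec$cv)
    noise <- if (spec$cv > 0) {
      exp(sig * stats::rnorm(n) - sig^2 / 2)
    } else rep(1, n)
    val <- mu * exp(off * sig) * noise
    if (any(spec$planted != 0)) {
      val <- val + spec$planted[cat_t] * noise_sd(spec, rec$aabc)
    }
    rec[[spec$name]] <- pmax(val, .Machine$double.eps)
  }
  rec
}

#' Generate a false-positive case table
#'
#' Per disease, assigns each case a collection category by a multinomial
#' draw over the configured shares and an AaBC hour uniform within that
#' category's range. Covariates are drawn within the reference ranges (term,
#' normal birth weight, no TPN) so the cases survive the reference filter.
#'
#' @param fp An [fp_model()].
#' @param seed Integer seed.
#' @return Tibble with columns `disease`, `id`, `aabc`, `category`, `ga`,
#'   `bw`, `sex`, `tpn`.
#' @export
generate_fp_cases <- function(fp, seed = 1L) {
  stopifnot(inherits(fp, "fp_model"))
  set.seed(sub_seed(seed, 1L))
  sch <- aabc_scheme()
  out <- list()
  for (i in seq_len(nrow(fp$diseases))) {
    row <- fp$diseases[i, ]
    total <- row$total_fp
    if (total == 0) next
    shares <- c(row$share_early, row$share_standard, row$share_late)
    counts <- as.vector(stats::rmultinom(1, total, shares))
    cats <- rep(c("early", "standard", "late"), counts)
    aabc <- vapply(cats, function(cat) {
      rng <- sch$categories[[cat]]
      sample(rng[1]:rng[2], 1L)
    }, integer(1))
    out[[i]] <- tibble::tibble(
      disease = row$disease,
      id = sprintf("FP-%s-%04d", row$disease, seq_len(total)),
      aabc = aabc, category = cats,
      ga = sample(37:41, total, replace = TRUE),
      bw = sample(2500:4000, total, replace = TRUE),
      sex = sample(c("male", "female"), total, replace = TRUE),
      tpn = "no"
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(disease = character(), id = character(),
                          aabc = integer(), category = character(),
                          ga = integer(), bw = integer(), sex = character(),
                          tpn = character()))
  }
  dplyr::bind_rows(out)
}
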