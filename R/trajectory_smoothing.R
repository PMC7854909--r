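# Penalized-spline smoothing of analyte level versus age at blood
# collection, with pointwise confidence bands and windowed stratum
# comparisons.

#' Smoother settings for trajectory fits
#'
#' Cubic penalized regression splines with about 15 basis functions and the
#' smoothing penalty chosen by generalized cross-validation; pointwise
#' normal-approximation confidence bands.
#'
#' @param k Basis dimension (reduced automatically when the data carry
#'   fewer distinct AaBC hours).
#' @param bs Spline basis, passed to [mgcv::s()].
#' @param method Penalty-selection criterion for [mgcv::gam()].
#' @param grid Integer AaBC hours at which the fit is evaluated.
#' @param min_n Minimum records required for a fit (sparse strata make the
#'   late-AaBC estimate unstable).
#' @param level Confidence level of the pointwise band.
#' @return An object of class `smoother_spec`.
#' @export
smoother_spec <- function(k = 15, bs = "cr", method = "GCV.Cp",
                          grid = 12:168, min_n = 200, level = 0.95) {
  stopifnot(k >= 4, level > 0, level < 1)
  structure(list(k = k, bs = bs, method = method, grid = as.integer(grid),
                 min_n = min_n, level = level),
            class = "smoother_spec")
}

#' Fit a smoothed analyte-versus-AaBC trajectory
#'
#' Penalized-spline estimate of the conditional mean analyte level as a
#' function of age at blood collection within one covariate stratum, with a
#' pointwise confidence band for the mean. The fit is deterministic: no
#' random initialization is involved.
#'
#' @param records Record tibble already filtered to the stratum of interest.
#' @param metabolite Analyte column to smooth.
#' @param stratum Optional label describing the stratum (carried through to
#'   outputs).
#' @param spec A [smoother_spec()].
#' @return An object of class `trajectory_fit`: list with `metabolite`,
#'   `stratum`, `grid`, `mean`, `ci_low`, `ci_high`, `n_used`, `spec` and
#'   the raw `(aabc, value)` data used.
#' @export
fit_trajectory <- function(records, metabolite, stratum = NULL,
                           spec = smoother_spec()) {
  if (!metabolite %in% names(records)) {
    stop("no column '", metabolite, "' in records", call. = FALSE)
  }
  dat <- data.frame(aabc = records$aabc, value = records[[metabolite]])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < spec$min_n) {
    stop("stratum holds ", nrow(dat), " records; at least ", spec$min_n,
         " are required for a stable trajectory fit", call. = FALSE)
  }
  n_unique <- length(unique(dat$aabc))
  if (n_unique < 5) {
    stop("AaBC has ", n_unique, " distinct hour(s); no spread to smooth over",
         call. = FALSE)
  }
  k_eff <- min(spec$k, n_unique)
  fit <- mgcv::gam(value ~ s(aabc, k = k_eff, bs = spec$bs), data = dat,
                   method = spec$method)
  grid <- spec$grid[spec$grid >= min(dat$aabc) & spec$grid <= max(dat$aabc)]
  pred <- mgcv::predict.gam(fit, newdata = data.frame(aabc = grid),
                            se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - spec$level) / 2)
  structure(
    list(metabolite = metabolite, stratum = stratum, grid = grid,
         mean = as.numeric(pred$fit),
         ci_low = as.numeric(pred$fit - z * pred$se.fit),
         ci_high = as.numeric(pred$fit + z * pred$se.fit),
         n_used = nrow(dat), spec = spec,
         data = tibble::tibble(aabc = dat$aabc, value = dat$value)),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Trajectory fit:", x$metabolite,
      if (!is.null(x$stratum)) paste0("[", x$stratum, "]") else "",
      "- n =", x$n_used, ", grid", min(x$grid), "-", max(x$grid), "h\n")
  invisible(x)
}

#' Trajectory fit as a tibble
#'
#' @param fit A [fit_trajectory()] result.
#' @return Tibble with columns `aabc`, `mean`, `ci_low`, `ci_high`.
#' @export
trajectory_table <- function(fit) {
  stopifnot(inherits(fit, "trajectory_fit"))
  tibble::tibble(aabc = fit$grid, mean = fit$mean,
                 ci_low = fit$ci_low, ci_high = fit$ci_high)
}

#' Compare two strata over an AaBC window
#'
#' The fitted-mean difference averaged over the grid points inside the
#' window, with a Welch two-sample test on the raw records falling in the
#' window supplying the p-value (the smoothed curves themselves are not
#' tested).
#'
#' @param fitA,fitB [fit_trajectory()] results for the same analyte.
#' @param window `c(lo, hi)` AaBC hours, inclusive.
#' @param alpha Significance level for the indicator.
#' @return Tibble with `mean_diff` (A minus B), `p`, `significant`,
#'   `window_lo`, `window_hi`, `n_a`, `n_b`.
#' @export
compare_strata <- function(fitA, fitB, window, alpha = 0.05) {
  stopifnot(inherits(fitA, "trajectory_fit"), inherits(fitB, "trajectory_fit"))
  if (!identical(fitA$metabolite, fitB$metabolite)) {
    stop("fits are for different analytes: ", fitA$metabolite, " vs ",
         fitB$metabolite, call. = FALSE)
  }
  if (length(window) != 2L || window[1] > window[2]) {
    stop("window must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  shared <- intersect(fitA$grid, fitB$grid)
  shared <- shared[shared >= window[1] & shared <= window[2]]
  if (length(shared) == 0) {
    stop("window [", window[1], ", ", window[2],
         "] does not overlap the shared fit grid: cannot align", call. = FALSE)
  }
  mean_diff <- mean(fitA$mean[match(shared, fitA$grid)] -
                    fitB$mean[match(shared, fitB$grid)])
  xa <- fitA$data$value[fitA$data$aabc >= window[1] &
                        fitA$data$aabc <= window[2]]
  xb <- fitB$data$value[fitB$data$aabc >= window[1] &
                        fitB$data$aabc <= window[2]]
  if (length(xa) < 2 || length(xb) < 2) {
    stop("fewer than 2 raw records in the window for one stratum",
         call. = FALSE)
  }
  p <- if (isTRUE(all.equal(c(xa, xb), rep(mean(c(xa, xb)), length(xa) +
                                           length(xb))))) {
    1  # both samples constant and equal: no evidence of difference
  } else {
    stats::t.test(xa, xb)$p.value
  }
  tibble::tibble(mean_diff = mean_diff, p = p, significant = p < alpha,
                 window_lo = window[1], window_hi = window[2],
                 n_a = length(xa), n_b = length(xb))
}
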