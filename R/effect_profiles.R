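# Cohen's d effect-size profiles across AaBC bins, marker flagging and
# two-cluster trajectory clustering.

#' Cohen's d between two samples
#'
#' The difference between the two group means divided by the pooled
#' standard deviation,
#' `s_pooled^2 = ((nx-1) sx^2 + (ny-1) sy^2) / (nx + ny - 2)`.
#' Positive values mean the comparison group `x` lies above the reference
#' group `y`. No small-sample bias correction is applied. Cohen's d is not
#' influenced by sample size, which lets groups of very different sizes be
#' compared directly.
#'
#' @param x Comparison sample (length >= 2).
#' @param y Reference sample (length >= 2).
#' @return Cohen's d (dimensionless scalar).
#' @export
cohen_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) {
    stop("cohen_d needs at least 2 observations per group", call. = FALSE)
  }
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) {
    stop("pooled standard deviation is zero: effect size undefined",
         call. = FALSE)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Analysis thresholds for marker flagging
#'
#' @param flag_threshold Absolute Cohen's d above which an analyte/bin cell
#'   is flagged (strict inequality). Default 0.2.
#' @param strong_threshold Threshold for strong effects. Default 0.5.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(flag_threshold = 0.2, strong_threshold = 0.5) {
  if (!(flag_threshold > 0 && flag_threshold < strong_threshold)) {
    stop("need 0 < flag_threshold < strong_threshold", call. = FALSE)
  }
  structure(list(flag_threshold = flag_threshold,
                 strong_threshold = strong_threshold),
            class = "analysis_config")
}

#' Metabolite-by-bin Cohen's d matrix
#'
#' In `"fine"` mode each of the nine 6-hour windows 18-72 h is compared to
#' the 12-17 h reference window; in `"category"` mode the early and late
#' windows are compared to the standard window. Records should already be
#' restricted to the reference subset ([restrict_reference()]) so GA, BW
#' and TPN do not confound the comparison.
#'
#' @param records Restricted record tibble.
#' @param scheme An [aabc_scheme()].
#' @param metabolites Analyte columns to use (default: all).
#' @param mode `"fine"` or `"category"`.
#' @return An object of class `effect_size_matrix`: list with `d`
#'   (metabolites x bins matrix), `n` (per-bin counts, reference included),
#'   `mode` and `reference`. Cells whose bin holds fewer than 2 values are
#'   `NA` and reported via a message.
#' @export
effect_matrix <- function(records, scheme = aabc_scheme(),
                          metabolites = NULL, mode = c("fine", "category")) {
  mode <- match.arg(mode)
  metabolites <- metabolites %||% metabolite_names(records)
  if (mode == "fine") {
    bin <- assign_fine_bin(records$aabc, scheme)
    keep <- !is.na(bin)
    groups <- factor(bin[keep], levels = 0:9,
                     labels = fine_bin_labels(scheme))
    ref_label <- fine_bin_labels(scheme)[scheme$reference_fine + 1L]
  } else {
    cat <- assign_category(records$aabc, scheme)
    keep <- !is.na(cat)
    groups <- factor(cat[keep], levels = c("early", "standard", "late"))
    ref_label <- scheme$reference_category
  }
  records <- records[keep, , drop = FALSE]
  n_by_bin <- table(groups)
  if (n_by_bin[[ref_label]] < 2) {
    stop("reference bin '", ref_label, "' holds fewer than 2 records",
         call. = FALSE)
  }
  comp_labels <- setdiff(levels(groups), ref_label)
  d <- matrix(NA_real_, nrow = length(metabolites),
              ncol = length(comp_labels),
              dimnames = list(metabolites, comp_labels))
  idx_by_bin <- split(seq_len(nrow(records)), groups)
  for (m in metabolites) {
    vals <- records[[m]]
    ref_vals <- vals[idx_by_bin[[ref_label]]]
    for (b in comp_labels) {
      cmp_vals <- vals[idx_by_bin[[b]]]
      if (length(cmp_vals) < 2) {
        message("empty or near-empty bin '", b, "' for ", m,
                ": cell left missing")
        next
      }
      d[m, b] <- cohen_d(cmp_vals, ref_vals)
    }
  }
  structure(list(d = d, n = stats::setNames(as.integer(n_by_bin),
                                            names(n_by_bin)),
                 mode = mode, reference = ref_label),
            class = "effect_size_matrix")
}

#' @export
print.effect_size_matrix <- function(x, ...) {
  cat("Effect-size matrix (Cohen's d), mode:", x$mode,
      "- reference:", x$reference, "\n")
  print(round(x$d, 3))
  invisible(x)
}

#' Flag analyte/bin cells with AaBC-related differences
#'
#' Cells with absolute Cohen's d strictly larger than the flag threshold.
#'
#' @param matrix An [effect_matrix()] result.
#' @param config An [analysis_config()].
#' @return Tibble with columns `metabolite`, `bin`, `d`, `direction`
#'   (`"positive"`/`"negative"`), `strong` (|d| >= strong threshold).
#' @export
flag_markers <- function(matrix, config = analysis_config()) {
  stopifnot(inherits(matrix, "effect_size_matrix"))
  d <- matrix$d
  hit <- which(!is.na(d) & abs(d) > config$flag_threshold, arr.ind = TRUE)
  dvals <- d[hit]
  tibble::tibble(
    metabolite = rownames(d)[hit[, 1]],
    bin = colnames(d)[hit[, 2]],
    d = dvals,
    direction = ifelse(dvals > 0, "positive", "negative"),
    strong = abs(dvals) >= config$strong_threshold
  )
}

#' Cluster analyte trajectory profiles into two groups
#'
#' Rows of a fine-mode effect-size matrix (nine Cohen's d values per
#' analyte) are clustered by agglomerative hierarchical clustering
#' (Euclidean distance, complete linkage) and cut into two clusters. The
#' cluster whose mean terminal-bin d is negative is labeled `"decreasing"`,
#' the other `"increasing"`. Missing cells are imputed by within-row linear
#' interpolation for clustering only.
#'
#' @param matrix A fine-mode [effect_matrix()] result with >= 2 rows.
#' @param method Linkage passed to [stats::hclust()].
#' @return List with `tree` (hclust), `labels` (named character per
#'   analyte), `order` (analyte names in dendrogram order).
#' @export
cluster_profiles <- function(matrix, method = "complete") {
  stopifnot(inherits(matrix, "effect_size_matrix"))
  d <- matrix$d
  if (nrow(d) < 2) stop("need at least 2 analytes to cluster", call. = FALSE)
  if (anyNA(d)) {
    message("imputing ", sum(is.na(d)), " missing cell(s) by row interpolation")
    d <- t(apply(d, 1, function(row) {
      if (all(is.na(row))) stop("analyte with no computed cells", call. = FALSE)
      if (anyNA(row)) {
        row <- stats::approx(seq_along(row), row, xout = seq_along(row),
                             rule = 2)$y
      }
      row
    }))
    colnames(d) <- colnames(matrix$d)
  }
  dist_d <- stats::dist(d, method = "euclidean")
  if (all(dist_d < .Machine$double.eps^0.5)) {
    warning("all trajectory profiles identical: degenerate clustering, ",
            "single cluster returned")
    tree <- stats::hclust(dist_d, method = method)
    labels <- stats::setNames(rep("increasing", nrow(d)), rownames(d))
    return(list(tree = tree, labels = labels,
                order = rownames(d)[tree$order]))
  }
  tree <- stats::hclust(dist_d, method = method)
  cut2 <- stats::cutree(tree, k = 2)
  terminal <- d[, ncol(d)]
  means <- tapply(terminal, cut2, mean)
  dec_cluster <- as.integer(names(means)[which.min(means)])
  labels <- ifelse(cut2 == dec_cluster, "decreasing", "increasing")
  names(labels) <- rownames(d)
  list(tree = tree, labels = labels, order = rownames(d)[tree$order])
}
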