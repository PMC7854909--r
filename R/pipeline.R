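# End-to-end pipeline: simulate -> filter -> profile -> trajectories ->
# fpstats -> report, with TSV artifacts and a provenance sidecar.

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order and writes every artifact under
#' `out_dir` as TSV (plus a markdown report and a JSON provenance sidecar
#' recording the configuration hash, seed and package version). Re-running
#' with the same configuration reproduces the artifacts byte for byte.
#'
#' Stages and artifacts:
#' \describe{
#'   \item{simulate}{`cohort.tsv`, `fp_cases.tsv` (when an fp model is
#'     configured)}
#'   \item{filter}{`cohort_filtered.tsv`, `exclusion_tally.tsv`,
#'     `cohort_reference.tsv`}
#'   \item{profile}{`effect_fine.tsv`, `effect_category.tsv`, `flags.tsv`,
#'     `clusters.tsv`}
#'   \item{trajectories}{`trajectory_<analyte>.tsv` per requested analyte}
#'   \item{fpstats}{`fp_counts.tsv`, `performance_table.tsv` (uses the
#'     simulated fp cases when present, otherwise the packaged published
#'     counts)}
#'   \item{report}{`report.md`}
#' }
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [generator_config()].
#' @param scheme An [aabc_scheme()].
#' @param filter_spec A [cohort_filter_spec()].
#' @param stages Character subset of the six stage names.
#' @param trajectory_metabolites Analytes to smooth in the trajectories
#'   stage.
#' @param trajectory_strata Named list of stratum definitions; each element
#'   is a function taking the filtered records and returning a logical keep
#'   vector.
#' @return Named character vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(out_dir,
                         config = generator_config(20000),
                         scheme = aabc_scheme(),
                         filter_spec = cohort_filter_spec(),
                         stages = c("simulate", "filter", "profile",
                                    "trajectories", "fpstats", "report"),
                         trajectory_metabolites = c("Phe", "C0"),
                         trajectory_strata = list(
                           term = function(r) r$ga >= 37 & r$ga <= 41,
                           preterm = function(r) r$ga <= 36)) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    artifacts[[name]] <<- path
    path
  }
  stage_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- NULL; fp_cases <- NULL; filtered <- NULL; reference <- NULL
  tally <- NULL; eff_fine <- NULL; eff_cat <- NULL; clusters <- NULL
  perf <- NULL; counts <- NULL

  if ("simulate" %in% stages) stage_guard("simulate", {
    cohort <- generate_cohort(config)
    emit("cohort.tsv", function(p) write_table(cohort, p))
    if (!is.null(config$fp)) {
      fp_cases <- generate_fp_cases(config$fp, seed = config$seed)
      emit("fp_cases.tsv", function(p) write_table(fp_cases, p))
    }
  })

  if ("filter" %in% stages) stage_guard("filter", {
    if (is.null(cohort)) stop("no cohort available (run simulate first)")
    ex <- apply_exclusions(cohort, filter_spec)
    filtered <- ex$records
    tally <- ex$tally
    message("exclusions: ", paste(names(tally), tally, sep = "=",
                                  collapse = ", "),
            "; retained ", nrow(filtered), " of ", nrow(cohort))
    reference <- restrict_reference(filtered, filter_spec)
    emit("cohort_filtered.tsv", function(p) write_table(filtered, p))
    emit("exclusion_tally.tsv", function(p)
      write_table(tibble::tibble(rule = names(tally),
                                 excluded = as.integer(tally)), p))
    emit("cohort_reference.tsv", function(p) write_table(reference, p))
  })

  if ("profile" %in% stages) stage_guard("profile", {
    if (is.null(reference)) stop("no reference cohort (run filter first)")
    eff_fine <- effect_matrix(reference, scheme, mode = "fine")
    eff_cat <- effect_matrix(reference, scheme, mode = "category")
    message("fine-bin counts: ", paste(eff_fine$n, collapse = ", "))
    emit("effect_fine.tsv", function(p) write_effect_matrix(eff_fine, p))
    emit("effect_category.tsv", function(p) write_effect_matrix(eff_cat, p))
    emit("flags.tsv", function(p) write_table(flag_markers(eff_cat), p))
    if (nrow(eff_fine$d) >= 2) {
      clusters <- cluster_profiles(eff_fine)
      emit("clusters.tsv", function(p)
        write_table(tibble::tibble(metabolite = names(clusters$labels),
                                   cluster = unname(clusters$labels)), p))
    }
  })

  if ("trajectories" %in% stages) stage_guard("trajectories", {
    if (is.null(filtered)) stop("no filtered cohort (run filter first)")
    for (m in trajectory_metabolites) {
      for (sname in names(trajectory_strata)) {
        keep <- trajectory_strata[[sname]](filtered)
        sub <- filtered[keep & !is.na(keep), , drop = FALSE]
        if (nrow(sub) < smoother_spec()$min_n) next
        fit <- fit_trajectory(sub, m, stratum = sname)
        safe <- gsub("[^A-Za-z0-9]+", "_", paste(m, sname, sep = "_"))
        emit(paste0("trajectory_", safe, ".tsv"),
             function(p) write_table(trajectory_table(fit), p))
      }
    }
  })

  if ("fpstats" %in% stages) stage_guard("fpstats", {
    ref_tabs <- load_reference_tables()
    if (!is.null(fp_cases)) {
      counts <- count_fp(fp_cases, neg_sizes = ref_tabs$neg_sizes,
                         scheme = scheme, filters = filter_spec)
      effects <- ref_tabs$effects[ref_tabs$effects$disease %in%
                                    counts$disease, ]
    } else {
      counts <- ref_tabs$counts
      effects <- ref_tabs$effects
    }
    perf <- performance_table(enrichment(counts), effects, ref_tabs$panel)
    emit("fp_counts.tsv", function(p) write_table(counts, p))
    emit("performance_table.tsv", function(p) write_table(perf, p))
  })

  if ("report" %in% stages) stage_guard("report", {
    emit("report.md", function(p) {
      lines <- c(
        "# Screening-timing analysis report", "",
        sprintf("Synthetic cohort: n = %d, seed = %d.", config$n_newborns,
                config$seed))
      if (!is.null(tally)) {
        lines <- c(lines, "",
                   "## Exclusions",
                   sprintf("- %s: %d", names(tally), as.integer(tally)),
                   sprintf("- retained: %d (reference subset: %d)",
                           nrow(filtered), nrow(reference)))
      }
      if (!is.null(eff_cat)) {
        fl <- flag_markers(eff_cat)
        lines <- c(lines, "",
                   "## Flagged analytes (|d| > 0.2, window vs standard)",
                   if (nrow(fl) == 0) "- none" else
                     sprintf("- %s [%s]: d = %.2f", fl$metabolite, fl$bin,
                             fl$d))
      }
      if (!is.null(clusters)) {
        tabs <- table(clusters$labels)
        lines <- c(lines, "",
                   "## Trajectory clusters",
                   sprintf("- %s: %d analytes", names(tabs),
                           as.integer(tabs)))
      }
      if (!is.null(perf)) {
        lines <- c(lines, "",
                   "## False-positive performance",
                   sprintf("- %s (%s%s): early %s / late %s", perf$disease,
                           perf$marker,
                           ifelse(perf$direction == "elevated", "+", "-"),
                           perf$call_early, perf$call_late))
      }
      writeLines(lines, p)
    })
  })

  emit("provenance.json", function(p) {
    cfg_file <- tempfile()
    on.exit(unlink(cfg_file))
    saveRDS(config, cfg_file, version = 2)
    jsonlite::write_json(
      list(config_hash = unname(tools::md5sum(cfg_file)),
           seed = config$seed,
           n_newborns = config$n_newborns,
           package_version = as.character(utils::packageVersion("nbstiming")),
           stages = stages,
           artifacts = sort(setdiff(names(artifacts), "provenance.json"))),
      p, auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(artifacts)
}
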