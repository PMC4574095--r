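#' Pipeline run configuration
#'
#' Bundles every tunable of a full simulate-reduce-analyze-meta run, all
#' defaulting to the pipeline's standard values: Evenson cut-points, the
#' 60/2-minute non-wear rule, 500 wear minutes in 07:00-22:59 for a valid
#' day, 3 valid days for inclusion. Every parameter is echoed into the run
#' report.
#'
#' @param simulate A [sim_config()] describing the cohort to generate, or
#'   `NULL` when `input_dir` points at an existing cohort directory.
#' @param input_dir Directory of epoch CSVs plus `demographics.csv`
#'   (as written by [simulate_cohort()]); ignored when `simulate` is given.
#' @param min_valid_days,cutpoints,nonwear_min_window,nonwear_max_interruption
#'   Reduction parameters, see [reduce_cohort()].
#' @param outcome Outcome column analysed, default `"mean_cpm"`.
#' @param formula_spec Regression structure, see [fit_adjusted_model()].
#' @param meta_group Grouping variable for the random-effects meta-analysis
#'   of the standardised sex gap, default `"country"`.
#' @param seed Seed for the run (overrides the simulate config's seed).
#' @param out_dir Optional directory for run outputs (summary CSVs,
#'   regression and forest tables, `report.json`).
#' @return A classed `run_config` list.
#' @export
run_config <- function(simulate = sim_config(), input_dir = NULL,
                       min_valid_days = 3L, cutpoints = pa_cutpoints(),
                       nonwear_min_window = 60L,
                       nonwear_max_interruption = 2L,
                       outcome = "mean_cpm",
                       formula_spec = "age_sex_interaction",
                       meta_group = "country", seed = NULL,
                       out_dir = NULL) {
  if (is.null(simulate) && is.null(input_dir)) {
    stop("either a simulate config or an input_dir is required",
         call. = FALSE)
  }
  if (!is.null(simulate) && !is.null(seed)) simulate$seed <- as.integer(seed)
  structure(list(simulate = simulate, input_dir = input_dir,
                 min_valid_days = as.integer(min_valid_days),
                 cutpoints = cutpoints,
                 nonwear_min_window = as.integer(nonwear_min_window),
                 nonwear_max_interruption =
                   as.integer(nonwear_max_interruption),
                 outcome = outcome, formula_spec = formula_spec,
                 meta_group = meta_group,
                 seed = if (is.null(seed)) simulate$seed else as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> reduce -> build records -> adjusted
#' regression -> within-country standardisation -> per-country sex-gap
#' models -> random-effects meta-analysis, and returns a run report with
#' per-stage record counts mirroring the data-reduction flow (participants
#' in, participants excluded for insufficient valid days, days excluded as
#' invalid), the full parameter echo and a content hash. Reruns with the
#' same config and seed are byte-identical.
#'
#' The per-country models and meta-analysis need at least two countries;
#' with fewer, those stages are skipped and noted in the report.
#'
#' @param config A [run_config()].
#' @return An object of class `pipeline_report`; if `config$out_dir` is set,
#'   also writes `days.csv`, `timepoints.csv`, `records.csv`,
#'   `regression.csv`, `meta_forest.csv` and `report.json` there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$simulate)) {
    cohort <- run_stage("simulate", simulate_cohort(config$simulate))
    demographics <- cohort$demographics
    truth <- cohort$truth
  } else {
    cohort <- run_stage("load", read_epoch_dir(config$input_dir))
    demographics <- run_stage("load", tibble::as_tibble(utils::read.csv(
      file.path(config$input_dir, "demographics.csv"),
      stringsAsFactors = FALSE)))
    truth <- NULL
  }

  red <- run_stage("reduce", reduce_cohort(
    cohort, config$min_valid_days, config$cutpoints,
    config$nonwear_min_window, config$nonwear_max_interruption))

  empty <- red$counts$timepoints_included == 0L
  records <- if (empty) NULL else
    run_stage("records", build_analysis_records(red$timepoints, demographics))

  regression <- NULL
  meta <- NULL
  per_country <- NULL
  if (!empty) {
    regression <- run_stage("analyze", fit_adjusted_model(
      records, outcome = config$outcome,
      formula_spec = config$formula_spec))
    groups <- unique(records[[config$meta_group]])
    if (length(groups) >= 2L &&
        all(table(records[[config$meta_group]]) >= 2L)) {
      records <- run_stage("standardize", standardize_within_country(
        records, config$outcome))
      zcol <- paste0(config$outcome, "_z")
      rows <- lapply(groups, function(g) {
        rc <- records[records[[config$meta_group]] == g, , drop = FALSE]
        if (length(unique(rc$sex)) < 2L ||
            length(unique(rc$cluster_id)) < 2L) return(NULL)
        sg <- tryCatch(
          suppressWarnings(sex_gap(fit_adjusted_model(
            rc, outcome = zcol, formula_spec = "main"))),
          error = function(e) NULL) # saturated or singular small groups
        if (is.null(sg) || !is.finite(sg$se) || sg$se <= 0) return(NULL)
        tibble::tibble(group = g, estimate = sg$estimate, se = sg$se)
      })
      per_country <- tibble::as_tibble(
        data.table::rbindlist(Filter(Negate(is.null), rows)))
      if (nrow(per_country) >= 2L) {
        meta <- run_stage("meta", meta_analyze(per_country$estimate,
                                               per_country$se,
                                               per_country$group))
      }
    }
  }

  cfg_echo <- config
  cfg_echo$cutpoints <- unclass(cfg_echo$cutpoints)
  if (!is.null(cfg_echo$simulate)) {
    cfg_echo$simulate$state_process <- NULL # closures are not serialisable
    cfg_echo$simulate <- unclass(cfg_echo$simulate)
  }
  report <- list(
    counts = red$counts,
    regression = if (!is.null(regression)) regression$coefficients,
    per_country_sex_gap = per_country,
    meta = if (!is.null(meta)) forest_data(meta),
    truth = if (!is.null(truth))
      truth[c("sex_gap_sd", "sex_gap_cpm", "annual_decline_pct")],
    config = unclass(cfg_echo),
    seed = config$seed,
    notes = if (empty) "all timepoints excluded; analysis stages skipped"
            else if (is.null(meta)) "meta stage skipped (< 2 groups)")
  report$hash <- rlang::hash(report)
  report <- structure(report, class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
      stop("pipeline stage 'write' failed: cannot create ", dir,
           call. = FALSE)
    }
    data.table::fwrite(red$days, file.path(dir, "days.csv"))
    data.table::fwrite(red$timepoints, file.path(dir, "timepoints.csv"))
    if (!is.null(records)) {
      data.table::fwrite(records, file.path(dir, "records.csv"))
    }
    if (!is.null(regression)) {
      data.table::fwrite(regression$coefficients,
                         file.path(dir, "regression.csv"))
    }
    if (!is.null(meta)) {
      data.table::fwrite(forest_data(meta), file.path(dir, "meta_forest.csv"))
    }
    jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  ct <- x$counts
  cat("<pipeline_report>\n")
  cat(sprintf("  participants: %d in, %d included\n", ct$participants_in,
              ct$participants_included))
  cat(sprintf("  timepoints:   %d in, %d included, %d excluded\n",
              ct$timepoints_in, ct$timepoints_included,
              ct$timepoints_excluded))
  cat(sprintf("  days:         %d measured, %d invalid (%.1f%%)\n",
              ct$days_measured, ct$days_invalid, ct$pct_days_invalid))
  if (!is.null(x$meta)) {
    p <- x$meta[x$meta$label == "pooled (RE)", ]
    cat(sprintf("  pooled sex gap: %.3f SD [%.3f, %.3f], I2 = %.1f%%\n",
                p$estimate, p$ci_low, p$ci_high, p$I2))
  }
  if (!is.null(x$notes)) cat("  note: ", x$notes, "\n", sep = "")
  cat("  hash: ", x$hash, "\n", sep = "")
  invisible(x)
}
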