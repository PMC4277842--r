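# End-to-end orchestration: simulate or load a cohort, apply the exclusion
# cascade, recode and predict, then validate each model overall and per
# year and (for two models) compare them. A pipeline run is a pure
# function of (inputs, config, seed).

#' Pipeline run configuration
#'
#' Either `cohort` (a data frame or a path to a cohort file) or
#' `simulate` (a [generator_config()]) supplies the admissions. Models
#' are [model_spec()]s (or paths to their JSON files); with a simulated
#' cohort and no models, the generator's own paired prediction sets are
#' validated.
#'
#' @param cohort cohort data frame or file path, or `NULL` to simulate.
#' @param simulate a `generator_config` used when `cohort` is `NULL`.
#' @param models list of `model_spec`s or JSON paths (0, 1 or 2 models).
#' @param mapping a [mapping_table()] or JSON path, used by the exclusion
#'   cascade's unmappable-diagnosis stage; optional.
#' @param stratification `"overall"`, `"by_year"` or `"both"`.
#' @param seed RNG seed for the simulated cohort.
#' @param out_dir directory to write reports into, or `NULL` to skip
#'   writing.
#' @param verbose print stage-level progress with record counts.
#' @return A `run_config`.
#' @export
run_config <- function(cohort = NULL, simulate = generator_config(),
                       models = list(), mapping = NULL,
                       stratification = c("both", "overall", "by_year"),
                       seed = NULL, out_dir = NULL, verbose = FALSE) {
  stratification <- match.arg(stratification)
  if (is.character(mapping)) mapping <- read_mapping_table(mapping)
  models <- lapply(models, function(m) {
    if (is.character(m)) read_model_spec(m) else m
  })
  if (length(models) > 2) stop("at most two models are compared")
  if (!is.null(seed) && !is.null(simulate)) simulate$seed <- as.integer(seed)
  structure(list(cohort = cohort, simulate = simulate, models = models,
                 mapping = mapping, stratification = stratification,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

pipeline_stage <- function(name, expr, verbose) {
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (verbose) message(sprintf("[%s] done", name))
  res
}

#' Run the validation pipeline end to end
#'
#' Stages, in order: obtain admissions (simulate or load), apply the
#' exclusion cascade, recode (effective location, sedation assumption),
#' predict with each model, validate per stratum, and compare the two
#' models where two are given. With an `out_dir` set, every report is
#' written as JSON alongside a human-readable performance grid
#' (see [format_report_grid()]).
#'
#' @param cfg a [run_config()].
#' @return List with `exclusion_report`, `reports` (list of
#'   `validation_report`s keyed `model/stratum`), `comparison` (DeLong
#'   results per stratum, when two models are run) and `records` (the
#'   analysis cohort).
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  v <- cfg$verbose

  preds_list <- NULL
  if (is.null(cfg$cohort)) {
    sim <- pipeline_stage("simulate", generate_cohort(cfg$simulate), v)
    records <- sim$records
    if (length(cfg$models) == 0) {
      preds_list <- list(sim$preds_true, sim$preds_distorted)
    }
  } else {
    records <- pipeline_stage("load", {
      if (is.character(cfg$cohort)) read_cohort(cfg$cohort) else cfg$cohort
    }, v)
  }

  excl <- pipeline_stage("exclusions",
                         apply_exclusions(records, mapping = cfg$mapping), v)
  if (v) message(sprintf("[exclusions] %d in, %d retained",
                         excl$report$total_in, excl$report$total_retained))
  cohort <- excl$records

  cohort <- pipeline_stage("recode", {
    cohort$location_prior <- recode_location(cohort$location_prior,
                                             cohort$previous_location,
                                             cohort$dataset_version)
    cohort$sedated <- assume_sedation(cohort$gcs_lowest)
    cohort
  }, v)

  if (length(cfg$models)) {
    preds_list <- pipeline_stage("predict",
      lapply(cfg$models, function(m) {
        ps <- predict(m, cohort)
        ps
      }), v)
  } else if (is.null(preds_list)) {
    stop("pipeline stage 'predict' failed: no models given and no simulated predictions")
  } else {
    # restrict the generator's prediction sets to the retained cohort
    preds_list <- lapply(preds_list, function(ps) {
      keep <- ps$admission_id %in% cohort$admission_id
      out <- ps[keep, , drop = FALSE]
      attr(out, "model_name") <- model_name(ps)
      out
    })
  }

  strata <- list()
  if (cfg$stratification %in% c("overall", "both")) {
    strata$overall <- cohort$admission_id
  }
  if (cfg$stratification %in% c("by_year", "both")) {
    for (ystr in stratify_by_year(cohort)) {
      strata[[as.character(ystr$year[1])]] <- ystr$admission_id
    }
  }

  reports <- list()
  comparison <- list()
  for (stratum in names(strata)) {
    ids <- strata[[stratum]]
    sub <- lapply(preds_list, function(ps) {
      out <- ps[ps$admission_id %in% ids, , drop = FALSE]
      attr(out, "model_name") <- model_name(ps)
      out
    })
    for (ps in sub) {
      reports[[paste(model_name(ps), stratum, sep = "/")]] <-
        pipeline_stage(paste0("validate ", model_name(ps), "/", stratum),
                       validate(ps), v)
    }
    if (length(sub) == 2) {
      comparison[[stratum]] <- pipeline_stage(
        paste0("compare/", stratum), delong_test(sub[[1]], sub[[2]]), v)
    }
  }

  result <- list(exclusion_report = excl$report, reports = reports,
                 comparison = if (length(comparison)) comparison,
                 records = cohort)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_exclusion_report(excl$report,
                           file.path(cfg$out_dir, "exclusion_report.json"))
    for (key in names(reports)) {
      fn <- paste0("report_", gsub("/", "_", key), ".json")
      write_validation_report(reports[[key]], file.path(cfg$out_dir, fn))
    }
    writeLines(format_report_grid(reports),
               file.path(cfg$out_dir, "performance_grid.txt"))
    if (length(comparison)) {
      jsonlite::write_json(comparison,
                           file.path(cfg$out_dir, "model_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  result
}

#' Format validation reports as a model-performance grid
#'
#' Lays out every measure (observed and expected mortality, c index,
#' Hosmer-Lemeshow, Cox calibration, Brier, R-squareds) for each model and
#' stratum in a fixed-width text table, one section per model, one column
#' per stratum.
#'
#' @param reports named list of `validation_report`s keyed
#'   `"model/stratum"`, as produced by [run_pipeline()].
#' @return Character vector of text lines.
#' @export
format_report_grid <- function(reports) {
  keys <- strsplit(names(reports), "/", fixed = TRUE)
  models <- unique(vapply(keys, `[`, character(1), 1))
  strata <- unique(vapply(keys, `[`, character(1), 2))
  fmt_ci <- function(x, ci, d = 3) {
    sprintf(paste0("%.", d, "f (%.", d, "f, %.", d, "f)"), x, ci[1], ci[2])
  }
  lines <- character(0)
  for (m in models) {
    lines <- c(lines, sprintf("== %s ==", m))
    rows <- list(
      "N" = function(r) format(r$n, big.mark = ","),
      "Observed mortality % (95% CI)" =
        function(r) fmt_ci(r$observed_mortality_pct, r$wilson_ci_95, 1),
      "Expected mortality %" = function(r) sprintf("%.1f", r$expected_mortality_pct),
      "c index (95% CI)" = function(r) fmt_ci(r$c_index, r$c_index_ci_95),
      "Hosmer-Lemeshow chi2 (P)" =
        function(r) sprintf("%.1f (%.3g)", r$hl_chi2, r$hl_p),
      "Cox intercept (95% CI)" =
        function(r) fmt_ci(r$cox_intercept, r$cox_intercept_ci_95, 2),
      "Cox slope (95% CI)" = function(r) fmt_ci(r$cox_slope, r$cox_slope_ci_95, 2),
      "Cox chi2 (P)" = function(r) sprintf("%.1f (%.3g)", r$cox_chi2, r$cox_p),
      "Brier score" = function(r) sprintf("%.3f", r$brier),
      "Sum-of-squares R2" = function(r) sprintf("%.3f", r$ss_r2),
      "Shapiro's R" = function(r) sprintf("%.3f", r$shapiro_r),
      "Entropy-based R2" = function(r) sprintf("%.3f", r$entropy_r2)
    )
    header <- sprintf("%-30s %s", "Measure",
                      paste(sprintf("%-22s", strata), collapse = " "))
    lines <- c(lines, header)
    for (lab in names(rows)) {
      cells <- vapply(strata, function(s) {
        r <- reports[[paste(m, s, sep = "/")]]
        if (is.null(r)) "-" else rows[[lab]](r)
      }, character(1))
      lines <- c(lines, sprintf("%-30s %s", lab,
                                paste(sprintf("%-22s", cells), collapse = " ")))
    }
    lines <- c(lines, "")
  }
  lines
}
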