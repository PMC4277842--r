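# Admission data model and the exclusion cascade. A cohort is a plain data
# frame with one row per critical-care admission, following a documented
# column dictionary; the cascade removes admissions in a fixed, auditable
# order and reconciles every count in an exclusion report.

#' Cohort column dictionary
#'
#' One row per column of a cohort file: name, type and meaning. Cohorts
#' are exchanged as comma-separated UTF-8 text with a header row and empty
#' fields for missing values.
#'
#' @return Data frame with columns `column`, `type`, `description`.
#' @export
cohort_dictionary <- function() {
  d <- rbind(
    c("admission_id", "character", "opaque unique admission token"),
    c("unit_id", "character", "opaque critical-care unit token"),
    c("year", "integer", "calendar year of admission"),
    c("age", "numeric", "age in years at admission (>= 16 for inclusion)"),
    c("sex", "character", "female | male"),
    c("surgical_status", "character",
      "elective_scheduled | emergency_urgent | nonsurgical"),
    c("location_prior", "character", "coded location prior to admission"),
    c("previous_location", "character",
      "location before location_prior, or empty"),
    c("dataset_version", "character", "v0 | v203"),
    c("cpr_24h", "logical", "CPR within 24h prior to admission"),
    c("highest_sbp", "numeric", "highest systolic BP, mmHg"),
    c("paired_dbp_at_highest", "numeric", "diastolic BP paired with highest SBP"),
    c("lowest_dbp", "numeric", "lowest diastolic BP, mmHg"),
    c("paired_sbp_at_lowest", "numeric", "systolic BP paired with lowest DBP"),
    c("ph_at_lowest_pao2", "numeric", "arterial pH at the lowest PaO2"),
    c("gcs_lowest", "integer", "lowest Glasgow Coma Score (3-15) or empty"),
    c("physiology_score", "integer", "physiology score, 0-100"),
    c("apache_score", "integer", "APACHE II score, 0-71, or empty"),
    c("diagnosis_code", "character", "source-system diagnosis token"),
    c("exclude_from_scoring", "logical",
      "flagged 'exclude from severity-of-illness scoring'"),
    c("exclude_reason", "character", "reason category for the flag, or empty"),
    c("is_readmission", "logical",
      "readmission within the same acute hospital stay"),
    c("hospital_mortality", "character", "died | survived | empty when missing")
  )
  out <- as.data.frame(d, stringsAsFactors = FALSE)
  names(out) <- c("column", "type", "description")
  out
}

EXCLUDE_REASONS <- c("apache_excluded", "low_risk", "other_team", "unspecified")

#' Validate a cohort data frame
#'
#' Checks the column dictionary, uniqueness of `admission_id` and the
#' per-record invariants (score ranges, paired blood pressures, coded
#' levels).
#'
#' @param records cohort data frame.
#' @return `records`, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(records) {
  need <- cohort_dictionary()$column
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$admission_id)) {
    stop("duplicate admission_id in cohort")
  }
  chk <- function(cond, msg) if (any(cond, na.rm = TRUE)) stop(msg)
  chk(records$physiology_score < 0 | records$physiology_score > 100,
      "physiology_score must be in 0-100")
  chk(records$apache_score < 0 | records$apache_score > 71,
      "apache_score must be in 0-71")
  chk(records$paired_dbp_at_highest > records$highest_sbp,
      "paired_dbp_at_highest must not exceed highest_sbp")
  chk(records$lowest_dbp > records$paired_sbp_at_lowest,
      "lowest_dbp must not exceed paired_sbp_at_lowest")
  chk(!records$sex %in% c("female", "male"), "sex must be female|male")
  chk(!records$hospital_mortality %in% c("died", "survived", NA),
      "hospital_mortality must be died|survived|missing")
  invisible(records)
}

#' Read / write a cohort as delimited text
#'
#' Comma-separated, UTF-8, header row; missing values are empty fields.
#' See [cohort_dictionary()] for the columns.
#'
#' @param path file path.
#' @param records cohort data frame.
#' @return `read_cohort` returns the cohort data frame; `write_cohort`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  for (col in c("cpr_24h", "exclude_from_scoring", "is_readmission")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  if ("admission_id" %in% names(df)) {
    df$admission_id <- as.character(df$admission_id)
  }
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

EXCLUSION_STAGES <- c(
  "flagged_exclude_from_scoring",
  "readmission_same_stay",
  "missing_outcome",
  "missing_age_location_or_diagnosis",
  "diagnosis_unmappable"
)

#' Apply the admission exclusion cascade
#'
#' Removes admissions in five fixed stages: (1) flagged 'exclude from
#' severity-of-illness scoring'; (2) readmissions of the same patient
#' within the same acute hospital stay; (3) missing hospital mortality;
#' (4) missing age, location prior to admission or primary diagnosis;
#' (5) diagnosis that cannot be mapped onto the hierarchical coding method
#' under the supplied mapping table. A record meeting several criteria is
#' counted only at the first stage that removes it, so the per-stage
#' counts and the retained total reconcile exactly.
#'
#' @param records cohort data frame (see [cohort_dictionary()]).
#' @param mapping a [mapping_table()] used by stage 5; with `NULL`,
#'   stage 5 removes nothing.
#' @param stage_order permutation of 1:5 giving the order in which the
#'   stage criteria are applied (default the documented order). Permuting
#'   stages can change per-stage counts but never the retained total.
#' @return List with `records` (the retained cohort) and `report` (an
#'   `exclusion_report`).
#' @export
apply_exclusions <- function(records, mapping = NULL, stage_order = 1:5) {
  stopifnot(setequal(stage_order, 1:5))
  if (anyDuplicated(records$admission_id)) {
    stop("duplicate admission_id in cohort")
  }
  n <- nrow(records)
  criteria <- list(
    records$exclude_from_scoring %in% TRUE,
    records$is_readmission %in% TRUE,
    is.na(records$hospital_mortality),
    is.na(records$age) | is.na(records$location_prior) |
      is.na(records$diagnosis_code),
    if (is.null(mapping)) rep(FALSE, n) else {
      !is.na(records$diagnosis_code) &
        map_resolution(records$diagnosis_code, mapping) == "unmapped"
    }
  )
  removed_at <- rep(0L, n)
  for (s in stage_order) {
    removed_at[removed_at == 0L & criteria[[s]]] <- s
  }
  per_stage <- data.frame(
    stage = EXCLUSION_STAGES[stage_order],
    removed = as.integer(tabulate(match(removed_at, stage_order), 5)),
    stringsAsFactors = FALSE
  )
  per_stage$remaining <- n - cumsum(per_stage$removed)

  # Table-1-style breakdown of the flagged records by reason category
  flagged <- records[removed_at != 0L &
                       records$exclude_from_scoring %in% TRUE, , drop = FALSE]
  reason <- flagged$exclude_reason
  unknown <- !is.na(reason) & !reason %in% EXCLUDE_REASONS
  if (any(unknown)) {
    warning("unknown exclude_reason categories bucketed as 'unspecified': ",
            paste(unique(reason[unknown]), collapse = ", "))
  }
  reason[is.na(reason) | unknown] <- "unspecified"
  per_reason <- as.data.frame(table(factor(reason, levels = EXCLUDE_REASONS)),
                              stringsAsFactors = FALSE)
  names(per_reason) <- c("reason", "count")

  report <- structure(list(
    total_in = n,
    per_stage = per_stage,
    per_reason = per_reason,
    total_retained = n - sum(per_stage$removed)
  ), class = "exclusion_report")
  list(records = records[removed_at == 0L, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d admissions in, %d retained (%.1f%%)\n",
              x$total_in, x$total_retained,
              100 * x$total_retained / max(x$total_in, 1)))
  for (i in seq_len(nrow(x$per_stage))) {
    cat(sprintf("  %-35s -%6d  -> %6d\n", x$per_stage$stage[i],
                x$per_stage$removed[i], x$per_stage$remaining[i]))
  }
  invisible(x)
}

#' Write / read an exclusion report as JSON
#' @param report an `exclusion_report`.
#' @param path file path.
#' @return `write_exclusion_report` returns `path` invisibly;
#'   `read_exclusion_report` the report.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_exclusion_report
#' @export
read_exclusion_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$per_stage <- as.data.frame(raw$per_stage)
  raw$per_reason <- as.data.frame(raw$per_reason)
  structure(raw, class = "exclusion_report")
}

#' Partition a cohort by calendar year
#'
#' @param records cohort data frame with a `year` column.
#' @return Named list of data frames, one per year present; the strata are
#'   disjoint and their union is the input.
#' @export
stratify_by_year <- function(records) {
  if (anyNA(records$year)) stop("every record needs a year")
  split(records, records$year)
}

#' Simulate the impact of category-wise random exclusions
#'
#' Emulates the effect of excluding a stated fraction of admissions of
#' given types (for example, the categories used to flag admissions out of
#' severity-of-illness scoring) on three headline measures: the c index,
#' the Brier score and the ratio of observed to expected deaths. Each
#' replication removes a random subset of the stated size per category and
#' recomputes the measures on the remaining admissions; results are
#' reported as percentage changes relative to the full cohort.
#'
#' @param records cohort data frame aligned with `preds` (same admissions,
#'   any order) carrying the category labels.
#' @param preds a [prediction_set()] on those admissions.
#' @param fractions named numeric vector, one fraction in `[0, 1]` per
#'   category to remove; names must match the category labels.
#' @param replications number of replications.
#' @param seed RNG seed.
#' @param category column name in `records` holding the category label
#'   (default `"impact_category"`), or a character vector of labels.
#' @return List with `replicates` (data frame: one row per replication
#'   with `delta_c_pct`, `delta_brier_pct`, `delta_oe_pct`) and `summary`
#'   (min/mean/max per measure).
#' @export
simulate_exclusion_impact <- function(records, preds, fractions,
                                      replications = 200, seed = 1,
                                      category = "impact_category") {
  stopifnot(inherits(preds, "prediction_set"))
  if (length(category) == 1L && category %in% names(records)) {
    labels <- records[[category]]
  } else if (length(category) == nrow(records)) {
    labels <- category
  } else {
    stop("`category` must name a column of records or give one label per record")
  }
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0, 1]")
  idx <- match(preds$admission_id, records$admission_id)
  if (anyNA(idx)) stop("preds contains admissions absent from records")
  labels <- labels[idx]

  measure <- function(ps) {
    c(c = delong_components(ps$predicted_risk, ps$outcome)$theta,
      brier = mean((ps$outcome - ps$predicted_risk)^2),
      oe = sum(ps$outcome) / sum(ps$predicted_risk))
  }
  base <- measure(preds)
  set.seed(seed)
  cats <- names(fractions)
  eligible <- lapply(cats, function(k) which(labels == k))
  names(eligible) <- cats
  for (k in cats) {
    if (fractions[k] > 0 && length(eligible[[k]]) == 0L) {
      warning("no records in category '", k, "'; skipping")
    }
  }
  reps <- vapply(seq_len(replications), function(r) {
    drop <- integer(0)
    for (k in cats) {
      n_k <- length(eligible[[k]])
      take <- round(fractions[k] * n_k)
      if (take > 0) drop <- c(drop, sample(eligible[[k]], take))
    }
    kept <- if (length(drop)) preds[-drop, , drop = FALSE] else preds
    100 * (measure(kept) - base) / base
  }, numeric(3))
  replicates <- data.frame(replication = seq_len(replications),
                           delta_c_pct = reps[1, ],
                           delta_brier_pct = reps[2, ],
                           delta_oe_pct = reps[3, ])
  summ <- t(apply(reps, 1, function(v) c(min = min(v), mean = mean(v),
                                         max = max(v))))
  rownames(summ) <- c("c_index", "brier", "oe_ratio")
  list(replicates = replicates, summary = as.data.frame(summ))
}
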