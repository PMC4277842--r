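# Harmonisation layer: recoding of location prior to admission, ordinary
# least-squares imputation of the lowest systolic blood pressure and lowest
# arterial pH, the sedation assumption for admissions without a recorded
# Glasgow Coma Score, and five-tier hierarchical diagnosis mapping.

LOCATION_CATEGORIES <- c(
  "emergency_department", "general_ward", "imaging", "recovery",
  "theatre", "other_critical_care", "other_hospital", "home", "clinic",
  "high_dependency_unit"
)

#' Recode location prior to admission
#'
#' Admissions from an imaging department or from a recovery area (used as a
#' temporary critical-care area) are weighted by the location they were in
#' before that. When the previous location was not recorded (legacy `v0`
#' dataset records, which captured a single location only), imaging-
#' department admissions are assumed to have come from an emergency
#' department and recovery-area admissions from a general ward — the most
#' common previous locations. All other categories pass through unchanged,
#' which also makes the recoding idempotent.
#'
#' @param location_prior coded location category (vectorised); see
#'   `LOCATION_CATEGORIES` for the known tokens.
#' @param previous_location coded location category or `NA` when absent.
#' @param dataset_version `"v0"` or `"v203"`; informational (the rule is
#'   driven by the presence of `previous_location`).
#' @return Character vector of effective location categories.
#' @export
recode_location <- function(location_prior, previous_location = NA,
                            dataset_version = "v0") {
  n <- length(location_prior)
  previous_location <- rep_len(previous_location, n)
  known <- c(LOCATION_CATEGORIES)
  bad <- !location_prior %in% known
  if (any(bad)) {
    stop("unknown location category: ", location_prior[which(bad)[1]])
  }
  bad_prev <- !is.na(previous_location) & !previous_location %in% known
  if (any(bad_prev)) {
    stop("unknown location category: ", previous_location[which(bad_prev)[1]])
  }
  out <- location_prior
  indirect <- location_prior %in% c("imaging", "recovery")
  use_prev <- indirect & !is.na(previous_location)
  out[use_prev] <- previous_location[use_prev]
  out[indirect & is.na(previous_location) & location_prior == "imaging"] <-
    "emergency_department"
  out[indirect & is.na(previous_location) & location_prior == "recovery"] <-
    "general_ward"
  out
}

#' Assume sedation from a missing Glasgow Coma Score
#'
#' Where sedation status is not recorded, admissions with no lowest
#' Glasgow Coma Score in the first 24 hours are assumed to have been
#' sedated (or paralysed and sedated); any recorded GCS, whatever its
#' value, implies the patient was assessable and therefore not sedated
#' for the entire period.
#'
#' @param gcs_lowest lowest Glasgow Coma Score, integer 3-15, or `NA`.
#' @return `"sedated"` or `"not_sedated"` (vectorised).
#' @export
assume_sedation <- function(gcs_lowest) {
  present <- !is.na(gcs_lowest)
  if (any(gcs_lowest[present] < 3 | gcs_lowest[present] > 15)) {
    stop("gcs_lowest must be in 3-15 when present")
  }
  ifelse(present, "not_sedated", "sedated")
}

IMPUTATION_PREDICTORS <- list(
  lowest_sbp = c("highest_sbp", "paired_dbp_at_highest",
                 "lowest_dbp", "paired_sbp_at_lowest"),
  lowest_ph = "ph_at_lowest_pao2"
)

IMPUTATION_CLAMP <- list(
  lowest_sbp = c(0, 300),   # mmHg
  lowest_ph = c(6.0, 8.0)   # pH units
)

#' Fit a regression imputation model for a physiology extreme
#'
#' Fits an ordinary least-squares regression of the unobserved extreme
#' value on its recorded surrogates, for use where a dataset records, e.g.,
#' only the highest systolic pressure with paired diastolic (and vice
#' versa) rather than the lowest systolic pressure itself, or only the pH
#' from the blood gas with the lowest PaO2 rather than the lowest pH.
#'
#' @param training data frame with the target and all its predictors
#'   observed. Predictors are fixed per target: for `lowest_sbp` they are
#'   `highest_sbp`, `paired_dbp_at_highest`, `lowest_dbp`,
#'   `paired_sbp_at_lowest`; for `lowest_ph`, `ph_at_lowest_pao2`.
#' @param target `"lowest_sbp"` or `"lowest_ph"`.
#' @return An `imputation_model`: coefficients (intercept + slopes),
#'   `fit_n` and `residual_sd`.
#' @export
fit_imputation_model <- function(training, target = c("lowest_sbp", "lowest_ph")) {
  target <- match.arg(target)
  preds <- IMPUTATION_PREDICTORS[[target]]
  need <- c(target, preds)
  missing_cols <- setdiff(need, names(training))
  if (length(missing_cols)) {
    stop("training data lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  complete <- stats::complete.cases(training[need])
  df <- training[complete, need, drop = FALSE]
  if (nrow(df) < length(preds) + 2) {
    stop("need at least ", length(preds) + 2, " complete training rows")
  }
  fml <- stats::reformulate(preds, response = target)
  fit <- stats::lm(fml, data = df)
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) {
    stop("degenerate (collinear) design; cannot fit imputation model")
  }
  rdf <- fit$df.residual
  structure(list(target = target,
                 predictor_names = preds,
                 coefficients = coefs,
                 fit_n = nrow(df),
                 residual_sd = sqrt(sum(stats::residuals(fit)^2) / rdf)),
            class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("<imputation_model> target %s, fit on %d rows, residual SD %.3g\n",
              x$target, x$fit_n, x$residual_sd))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Impute a physiology extreme from its surrogates
#'
#' Deterministic linear prediction from a fitted [fit_imputation_model()],
#' clamped to a physiological range (systolic blood pressure 0-300 mmHg;
#' pH 6.0-8.0) so that an extrapolated prediction can never propagate a
#' physiologically impossible value into scoring.
#'
#' @param records data frame with the model's predictor columns present
#'   and non-missing.
#' @param model an `imputation_model`.
#' @return Numeric vector of imputed values (mmHg or pH units).
#' @export
impute_extreme <- function(records, model) {
  stopifnot(inherits(model, "imputation_model"))
  for (p in model$predictor_names) {
    if (!p %in% names(records) || anyNA(records[[p]])) {
      stop("missing predictor for imputation: ", p)
    }
  }
  x <- as.matrix(records[model$predictor_names])
  pred <- unname(drop(cbind(1, x) %*% model$coefficients))
  rng <- IMPUTATION_CLAMP[[model$target]]
  clamp(pred, rng[1], rng[2])
}

#' Write / read an imputation model as JSON
#' @param model an `imputation_model`.
#' @param path file path.
#' @return `write_imputation_model` returns `path` invisibly;
#'   `read_imputation_model` the model.
#' @export
write_imputation_model <- function(model, path) {
  stopifnot(inherits(model, "imputation_model"))
  out <- unclass(model)
  out$coefficients <- as.list(out$coefficients)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_imputation_model
#' @export
read_imputation_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coefficients <- unlist(raw$coefficients)
  structure(raw[c("target", "predictor_names", "coefficients",
                  "fit_n", "residual_sd")],
            class = "imputation_model")
}

# ---- five-tier hierarchical diagnosis coding --------------------------

CODE_TIERS <- c("type_tier", "system_tier", "site_tier",
                "process_tier", "condition_tier")

#' Construct a five-tier hierarchical diagnosis code
#'
#' Reasons for admission are coded in a five-tier hierarchy: type
#' (surgical / nonsurgical), body system, anatomical site, pathological or
#' physiological process, and individual condition. Tiers are strictly
#' nested — a populated lower tier requires every higher tier populated —
#' and the code's resolution is its deepest populated tier. Coding to at
#' least the system tier is required to assign a model weight; a code
#' without a body system is `unmapped`.
#'
#' @param type_tier `"surgical"`, `"nonsurgical"` or `NA`.
#' @param system_tier,site_tier,process_tier,condition_tier tier tokens or
#'   `NA` when absent.
#' @return A `hierarchical_code` with a `resolution` field in
#'   `{condition, process, site, system, unmapped}`.
#' @export
hierarchical_code <- function(type_tier = NA, system_tier = NA, site_tier = NA,
                              process_tier = NA, condition_tier = NA) {
  tiers <- c(type_tier = type_tier, system_tier = system_tier,
             site_tier = site_tier, process_tier = process_tier,
             condition_tier = condition_tier)
  pop <- !is.na(tiers) & tiers != ""
  if (any(pop) && !all(pop[seq_len(max(which(pop)))])) {
    stop("tiers must be nested: a populated lower tier requires all higher tiers")
  }
  if (!is.na(type_tier) && !type_tier %in% c("surgical", "nonsurgical")) {
    stop("type_tier must be 'surgical' or 'nonsurgical'")
  }
  depth <- sum(pop)
  resolution <- if (depth < 2) "unmapped" else {
    c("unmapped", "system", "site", "process", "condition")[depth]
  }
  structure(list(type_tier = type_tier, system_tier = system_tier,
                 site_tier = site_tier, process_tier = process_tier,
                 condition_tier = condition_tier, resolution = resolution),
            class = "hierarchical_code")
}

#' @export
print.hierarchical_code <- function(x, ...) {
  cat(sprintf("<hierarchical_code> %s [resolution: %s]\n",
              paste(code_tiers(x), collapse = "/"), x$resolution))
  invisible(x)
}

# populated tier tokens in order, e.g. c("nonsurgical", "respiratory")
code_tiers <- function(code) {
  vals <- unlist(code[CODE_TIERS], use.names = FALSE)
  vals[!is.na(vals) & vals != ""]
}

#' An explicitly unmappable diagnosis code
#' @return A `hierarchical_code` with resolution `"unmapped"`.
#' @export
unmapped_code <- function() hierarchical_code()

#' Construct a diagnosis mapping table
#'
#' Maps source-system diagnosis tokens to five-tier hierarchical codes.
#' Tokens mapped to [unmapped_code()] are declared unmappable; tokens
#' absent from the table are treated the same way by [map_diagnosis()].
#'
#' @param entries named list of [hierarchical_code()]s, keyed by source
#'   diagnosis token.
#' @param provenance free-text note on where the mapping came from.
#' @return A `mapping_table`.
#' @export
mapping_table <- function(entries, provenance = "") {
  if (length(entries)) {
    if (is.null(names(entries)) || anyDuplicated(names(entries))) {
      stop("entries must be uniquely named by source diagnosis token")
    }
    ok <- vapply(entries, inherits, logical(1), "hierarchical_code")
    if (!all(ok)) stop("every entry must be a hierarchical_code")
  }
  structure(list(entries = entries, provenance = provenance),
            class = "mapping_table")
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("<mapping_table> %d source tokens (%s)\n",
              length(x$entries), x$provenance))
  print(mapping_coverage(x))
  invisible(x)
}

#' Map a source diagnosis token to its hierarchical code
#'
#' @param token source-system diagnosis token (scalar).
#' @param table a [mapping_table()].
#' @return The mapped `hierarchical_code`; tokens absent from the table
#'   return a code with resolution `"unmapped"` (an ordinary value, so the
#'   exclusion cascade can count it, not an error).
#' @export
map_diagnosis <- function(token, table) {
  stopifnot(inherits(table, "mapping_table"), length(token) == 1L)
  if (is.na(token) || !token %in% names(table$entries)) return(unmapped_code())
  table$entries[[token]]
}

# vectorised resolution lookup used by the exclusion cascade
map_resolution <- function(tokens, table) {
  res <- vapply(table$entries, function(e) e$resolution, character(1))
  out <- unname(res[match(tokens, names(table$entries))])
  out[is.na(out)] <- "unmapped"
  out
}

#' Mapping-table coverage by resolution tier
#'
#' @param table a [mapping_table()].
#' @return Data frame with one row per resolution tier (condition, process,
#'   site, system, unmapped): `count` and `pct` (percentages rounded to
#'   integers).
#' @export
mapping_coverage <- function(table) {
  stopifnot(inherits(table, "mapping_table"))
  lev <- c("condition", "process", "site", "system", "unmapped")
  res <- factor(vapply(table$entries, function(e) e$resolution, character(1)),
                levels = lev)
  counts <- as.integer(table(res))
  total <- sum(counts)
  data.frame(resolution = lev, count = counts,
             pct = if (total > 0) as.integer(round(100 * counts / total))
                   else rep(0L, 5))
}

#' Write / read a mapping table as JSON
#'
#' The five-tier nesting is stored with explicit tier fields per entry;
#' absent tiers are `null`.
#'
#' @param table a `mapping_table`.
#' @param path file path.
#' @return `write_mapping_table` returns `path` invisibly;
#'   `read_mapping_table` the `mapping_table`.
#' @export
write_mapping_table <- function(table, path) {
  stopifnot(inherits(table, "mapping_table"))
  entries <- lapply(table$entries, function(e) {
    tiers <- e[CODE_TIERS]
    tiers[vapply(tiers, is.na, logical(1))] <- list(NULL)
    tiers
  })
  jsonlite::write_json(list(provenance = table$provenance, entries = entries),
                       path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_mapping_table
#' @export
read_mapping_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(raw$entries, function(e) {
    a <- function(f) if (is.null(e[[f]])) NA else e[[f]]
    hierarchical_code(a("type_tier"), a("system_tier"), a("site_tier"),
                      a("process_tier"), a("condition_tier"))
  })
  mapping_table(entries, provenance = raw$provenance %||% "")
}
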