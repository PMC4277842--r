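#' Construct a prediction set
#'
#' A prediction set pairs, for one risk model, each admission's predicted
#' risk of acute hospital death with the observed binary outcome. It is the
#' common currency of every performance statistic in the package.
#'
#' Log-odds are clamped at +/- 35 so that predicted risks are strictly
#' inside (0, 1); exactly one of `predicted_risk` and `log_odds` may be
#' supplied, the other is derived through the logistic link.
#'
#' @param admission_id character or integer vector of unique admission
#'   identifiers.
#' @param outcome observed acute hospital mortality, coded 0 (survived) /
#'   1 (died); logical vectors are accepted.
#' @param predicted_risk predicted probability of death, in (0, 1).
#' @param log_odds predicted log-odds of death; alternative to
#'   `predicted_risk`.
#' @param model_name label for the model that produced the predictions.
#' @return An object of class `prediction_set`: a data frame with columns
#'   `admission_id`, `log_odds`, `predicted_risk` and `outcome`, plus a
#'   `model_name` attribute.
#' @examples
#' ps <- prediction_set(1:4, outcome = c(0, 1, 0, 1),
#'                      predicted_risk = c(0.1, 0.8, 0.3, 0.6))
#' c_index(ps)
#' @export
prediction_set <- function(admission_id, outcome, predicted_risk = NULL,
                           log_odds = NULL, model_name = "model") {
  if (is.null(predicted_risk) == is.null(log_odds)) {
    stop("supply exactly one of `predicted_risk` or `log_odds`")
  }
  if (anyDuplicated(admission_id)) {
    stop("duplicate admission_id in prediction set")
  }
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0L, 1L))) {
    stop("outcome must be coded 0 (survived) / 1 (died)")
  }
  if (is.null(log_odds)) {
    if (any(predicted_risk <= 0 | predicted_risk >= 1)) {
      predicted_risk <- clamp_prob(predicted_risk)
    }
    log_odds <- logit(predicted_risk)
  } else {
    log_odds <- clamp_log_odds(log_odds)
    predicted_risk <- inv_logit(log_odds)
  }
  n <- length(admission_id)
  stopifnot(length(outcome) == n, length(log_odds) == n)
  out <- data.frame(
    admission_id = as.character(admission_id),
    log_odds = as.numeric(log_odds),
    predicted_risk = as.numeric(predicted_risk),
    outcome = as.integer(outcome),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("prediction_set", "data.frame"),
            model_name = model_name)
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> model '%s': %d admissions, %d deaths (%.1f%%), mean risk %.3f\n",
              model_name(x), nrow(x), sum(x$outcome),
              100 * mean(x$outcome), mean(x$predicted_risk)))
  invisible(x)
}

#' Model name of a prediction set
#' @param x a `prediction_set`.
#' @return The model label as a character scalar.
#' @export
model_name <- function(x) attr(x, "model_name") %||% "model"

as_plain_df <- function(ps) {
  out <- as.data.frame(ps)
  class(out) <- "data.frame"
  out
}

#' Read / write prediction sets as delimited text
#'
#' Comma-separated, UTF-8, header row, columns `admission_id`, `log_odds`,
#' `predicted_risk`, `outcome`.
#'
#' @param path file path.
#' @param ps a `prediction_set`.
#' @param model_name model label to attach on read (defaults to the file
#'   name without extension).
#' @return `read_prediction_set` returns a `prediction_set`;
#'   `write_prediction_set` returns `path` invisibly.
#' @export
read_prediction_set <- function(path, model_name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("admission_id", "outcome")
  if (!all(req %in% names(df))) {
    stop("prediction set file must have columns admission_id and outcome")
  }
  nm <- model_name %||% sub("\\.[^.]*$", "", basename(path))
  if ("log_odds" %in% names(df)) {
    prediction_set(df$admission_id, df$outcome, log_odds = df$log_odds,
                   model_name = nm)
  } else {
    prediction_set(df$admission_id, df$outcome,
                   predicted_risk = df$predicted_risk, model_name = nm)
  }
}

#' @rdname read_prediction_set
#' @export
write_prediction_set <- function(ps, path) {
  stopifnot(inherits(ps, "prediction_set"))
  utils::write.csv(as_plain_df(ps), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
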