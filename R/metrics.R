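# Performance statistics for externally validating a binary risk model:
# discrimination (c index, DeLong comparison), calibration (Hosmer-Lemeshow
# in risk deciles, Cox calibration regression) and overall accuracy (Brier
# score, Shapiro's R and their scaled R-squared analogues), plus Wilson
# score intervals for observed mortality.

# DeLong structural components, computed with midranks in O(n log n).
# Returns the c index estimate and the per-subject components V10 (deaths)
# and V01 (survivors); ties contribute one half.
delong_components <- function(risk, outcome) {
  m <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  if (m == 0L || n0 == 0L) {
    stop("c index requires at least one death and one survivor")
  }
  r_all <- rank(risk, ties.method = "average")
  r_x <- rank(risk[outcome == 1L], ties.method = "average")
  r_y <- rank(risk[outcome == 0L], ties.method = "average")
  v10 <- (r_all[outcome == 1L] - r_x) / n0
  v01 <- 1 - (r_all[outcome == 0L] - r_y) / m
  list(theta = mean(v10), v10 = v10, v01 = v01, m = m, n0 = n0)
}

#' Concordance index (area under the ROC curve)
#'
#' The c index is the probability that a randomly chosen death received a
#' higher predicted risk than a randomly chosen survivor, with tied
#' predictions counted one half. The standard error and the symmetric 95%
#' confidence interval come from the DeLong structural-component variance.
#'
#' @param preds a [prediction_set()].
#' @param level confidence level for the interval.
#' @return A list with `value`, `se` and `ci_95` (length-2 numeric).
#' @references DeLong, DeLong and Clarke-Pearson's nonparametric approach
#'   to comparing correlated ROC areas.
#' @export
c_index <- function(preds, level = 0.95) {
  stopifnot(inherits(preds, "prediction_set"))
  dc <- delong_components(preds$predicted_risk, preds$outcome)
  # var() needs >= 2 observations in each class for a finite estimate
  s10 <- if (dc$m > 1L) stats::var(dc$v10) else 0
  s01 <- if (dc$n0 > 1L) stats::var(dc$v01) else 0
  se <- sqrt(s10 / dc$m + s01 / dc$n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(value = dc$theta, se = se,
       ci_95 = clamp(dc$theta + c(-1, 1) * z * se, 0, 1))
}

#' Paired comparison of two c indices (DeLong test)
#'
#' Compares the c indices of two models evaluated on the same admissions
#' with identical outcomes, using the paired variance of the difference
#' built from the DeLong structural components.
#'
#' @param preds_a,preds_b [prediction_set()]s covering the identical
#'   admission list with identical outcomes. Rows are aligned by
#'   `admission_id`.
#' @return A list with `c_a`, `c_b`, `difference`, `variance`, `z` and
#'   `p_two_sided`.
#' @export
delong_test <- function(preds_a, preds_b) {
  stopifnot(inherits(preds_a, "prediction_set"),
            inherits(preds_b, "prediction_set"))
  idx <- match(preds_a$admission_id, preds_b$admission_id)
  if (anyNA(idx) || nrow(preds_a) != nrow(preds_b)) {
    stop("prediction sets must cover the identical admission list; ",
         "restrict both to the common admissions first")
  }
  b <- preds_b[idx, ]
  if (!identical(preds_a$outcome, b$outcome)) {
    stop("outcomes differ between the two prediction sets")
  }
  ca <- delong_components(preds_a$predicted_risk, preds_a$outcome)
  cb <- delong_components(b$predicted_risk, b$outcome)
  d10 <- ca$v10 - cb$v10
  d01 <- ca$v01 - cb$v01
  var_diff <- (if (ca$m > 1L) stats::var(d10) else 0) / ca$m +
    (if (ca$n0 > 1L) stats::var(d01) else 0) / ca$n0
  diff <- ca$theta - cb$theta
  z <- if (var_diff == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / sqrt(var_diff)
  }
  list(c_a = ca$theta, c_b = cb$theta, difference = diff,
       variance = var_diff, z = z,
       p_two_sided = 2 * stats::pnorm(-abs(z)))
}

# Group assignment in near-equal quantile groups of predicted survival
# probability. Admissions with identical predicted risk are kept together
# (the group of the first tied position), so groups may be unequal but the
# assignment is deterministic and order-independent.
risk_group_index <- function(risk, n_groups) {
  n <- length(risk)
  ord <- order(risk)          # ascending death risk == descending survival
  g_sorted <- ceiling(seq_len(n) * n_groups / n)
  sorted_risk <- risk[ord]
  g_sorted <- g_sorted[match(sorted_risk, sorted_risk)]  # ties share a group
  g <- integer(n)
  g[ord] <- g_sorted
  g
}

#' Ten-group calibration table
#'
#' Splits the cohort into `n_groups` near-equal groups by predicted
#' probability and tabulates, per group, the size, mean predicted risk,
#' observed deaths and expected deaths (the sum of predicted risks).
#'
#' @inheritParams c_index
#' @param n_groups number of groups (default 10).
#' @return A `calibration_table`: data frame with columns `group`, `n`,
#'   `mean_risk`, `observed`, `expected`.
#' @export
calibration_groups <- function(preds, n_groups = 10) {
  stopifnot(inherits(preds, "prediction_set"), n_groups >= 2)
  g <- risk_group_index(preds$predicted_risk, n_groups)
  out <- data.frame(
    group = seq_len(n_groups),
    n = as.integer(tabulate(g, n_groups)),
    mean_risk = as.numeric(tapply(preds$predicted_risk, factor(g, seq_len(n_groups)), mean)),
    observed = as.integer(tapply(preds$outcome, factor(g, seq_len(n_groups)), sum)),
    expected = as.numeric(tapply(preds$predicted_risk, factor(g, seq_len(n_groups)), sum))
  )
  out$observed[is.na(out$observed)] <- 0L
  out$expected[is.na(out$expected)] <- 0
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Hosmer-Lemeshow test in equal-sized risk groups
#'
#' Chi-squared comparison of observed and expected deaths in `n_groups`
#' near-equal groups ordered by predicted probability. The degrees of
#' freedom equal the number of groups, the convention for external
#' validation where the model was fitted on independent data.
#'
#' @inheritParams calibration_groups
#' @return A list with `chi2`, `df`, `p` and the `calibration_table`.
#' @export
hosmer_lemeshow <- function(preds, n_groups = 10) {
  tab <- calibration_groups(preds, n_groups)
  occ <- tab$n > 0   # ties can empty a group; empty groups contribute nothing
  pi_bar <- tab$mean_risk
  if (any(occ & (pi_bar <= 0 | pi_bar >= 1))) {
    stop("a group has mean predicted risk of 0 or 1; try fewer groups")
  }
  chi2 <- sum(((tab$observed - tab$expected)^2 /
                 (tab$n * pi_bar * (1 - pi_bar)))[occ])
  df <- n_groups
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       table = tab)
}

#' Cox calibration regression
#'
#' Fits a maximum-likelihood logistic regression of observed survival on the
#' model's predicted log-odds of survival. Perfect linear calibration on the
#' log-odds scale corresponds to intercept 0 and slope 1; the joint
#' departure is tested by a likelihood-ratio chi-squared with 2 degrees of
#' freedom against the fixed (0, 1) model.
#'
#' @inheritParams c_index
#' @return A list with `intercept`, `slope`, `intercept_ci_95`,
#'   `slope_ci_95`, `chi2`, `df` (always 2) and `p`.
#' @export
cox_calibration <- function(preds, level = 0.95) {
  stopifnot(inherits(preds, "prediction_set"))
  y_surv <- 1L - preds$outcome
  if (all(y_surv == 0L) || all(y_surv == 1L)) {
    stop("both outcome classes must be present")
  }
  lo_surv <- -preds$log_odds   # predicted log odds of survival
  fit <- stats::glm(y_surv ~ lo_surv, family = stats::binomial())
  if (!fit$converged) {
    stop("Cox calibration regression did not converge after ",
         fit$iter, " IRLS iterations")
  }
  mu <- fit$fitted.values
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    stop("complete separation in Cox calibration regression")
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  # deviance of the fixed intercept-0 / slope-1 model (the model's own
  # predictions taken at face value)
  p0 <- clamp_prob(stats::plogis(lo_surv))
  dev0 <- -2 * sum(y_surv * log(p0) + (1 - y_surv) * log(1 - p0))
  chi2 <- max(dev0 - fit$deviance, 0)
  list(intercept = unname(est[1]), slope = unname(est[2]),
       intercept_ci_95 = unname(est[1] + c(-1, 1) * z * se[1]),
       slope_ci_95 = unname(est[2] + c(-1, 1) * z * se[2]),
       chi2 = chi2, df = 2,
       p = stats::pchisq(chi2, 2, lower.tail = FALSE))
}

#' Brier score and sum-of-squares R-squared
#'
#' The Brier score is the mean squared difference between the binary
#' outcome and the predicted probability. The sum-of-squares R-squared
#' scales it against a null model that assigns every admission the cohort
#' death rate: `ss_r2 = 1 - brier / brier_null`.
#'
#' @inheritParams c_index
#' @return A numeric scalar.
#' @export
brier_score <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  mean((preds$outcome - preds$predicted_risk)^2)
}

#' @rdname brier_score
#' @export
ss_r2 <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  p_bar <- mean(preds$outcome)
  brier_null <- mean((preds$outcome - p_bar)^2)
  1 - brier_score(preds) / brier_null
}

#' Shapiro's R and entropy-based R-squared
#'
#' Shapiro's R is the geometric mean of the probability the model assigned
#' to the outcome that actually occurred. The entropy-based R-squared
#' scales its logarithm against the null model assigning the cohort death
#' rate: `entropy_r2 = 1 - log(R) / log(R_null)`.
#'
#' @inheritParams c_index
#' @return A numeric scalar.
#' @export
shapiro_r <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  p_event <- clamp_prob(ifelse(preds$outcome == 1L,
                               preds$predicted_risk,
                               1 - preds$predicted_risk))
  exp(mean(log(p_event)))
}

#' @rdname shapiro_r
#' @export
entropy_r2 <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  p_bar <- clamp_prob(mean(preds$outcome))
  r <- shapiro_r(preds)
  r_null <- exp(mean(log(ifelse(preds$outcome == 1L, p_bar, 1 - p_bar))))
  1 - log(r) / log(r_null)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k number of events (successes).
#' @param n number of trials, at least 1.
#' @param level confidence level (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`, as proportions in `[0, 1]`.
#' @examples
#' round(100 * wilson_ci(6907, 23269), 1)  # 29.1 30.3
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (length(n) != 1L || n < 1) stop("n must be a single count >= 1")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p_hat <- k / n
  centre <- p_hat + z^2 / (2 * n)
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  clamp(c(lower = (centre - half) / denom, upper = (centre + half) / denom),
        0, 1)
}

#' ROC curve points
#'
#' Returns the operating points of the ROC curve at every distinct
#' prediction threshold, ordered from (0, 0) to (1, 1). The trapezoidal
#' area under these points equals the c index under the half-tie
#' convention.
#'
#' @inheritParams c_index
#' @return Data frame with columns `fpr` (1 - specificity) and `tpr`
#'   (sensitivity).
#' @export
roc_points <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  y <- preds$outcome
  m <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (m == 0L || n0 == 0L) stop("both outcome classes must be present")
  ord <- order(preds$predicted_risk, decreasing = TRUE)
  ys <- y[ord]
  ps <- preds$predicted_risk[ord]
  last_of_run <- c(ps[-1] != ps[-length(ps)], TRUE)
  tp <- cumsum(ys)[last_of_run]
  fp <- cumsum(1L - ys)[last_of_run]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / m))
}

#' Full validation report for one model on one cohort stratum
#'
#' Aggregates every performance statistic into a single report: observed
#' and expected mortality with a Wilson interval, the c index with DeLong
#' confidence interval, the Hosmer-Lemeshow test, Cox calibration
#' regression, the Brier score and Shapiro's R with their scaled
#' R-squared analogues.
#'
#' @inheritParams c_index
#' @param n_groups groups for the Hosmer-Lemeshow test.
#' @return A `validation_report` (list) whose fields mirror a standard
#'   model-performance table; see [report_to_row()] for a flat view.
#' @export
validate <- function(preds, n_groups = 10) {
  stopifnot(inherits(preds, "prediction_set"))
  n <- nrow(preds)
  deaths <- sum(preds$outcome)
  wil <- wilson_ci(deaths, n)
  ci <- c_index(preds)
  hl <- hosmer_lemeshow(preds, n_groups)
  cox <- cox_calibration(preds)
  rep <- list(
    model_name = model_name(preds),
    n = n,
    observed_deaths = deaths,
    observed_mortality_pct = 100 * deaths / n,
    wilson_ci_95 = unname(100 * wil),
    expected_mortality_pct = 100 * mean(preds$predicted_risk),
    c_index = ci$value, c_index_se = ci$se, c_index_ci_95 = ci$ci_95,
    hl_chi2 = hl$chi2, hl_df = hl$df, hl_p = hl$p,
    cox_intercept = cox$intercept, cox_intercept_ci_95 = cox$intercept_ci_95,
    cox_slope = cox$slope, cox_slope_ci_95 = cox$slope_ci_95,
    cox_chi2 = cox$chi2, cox_df = cox$df, cox_p = cox$p,
    brier = brier_score(preds),
    ss_r2 = ss_r2(preds),
    shapiro_r = shapiro_r(preds),
    entropy_r2 = entropy_r2(preds),
    calibration_table = hl$table
  )
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> model '%s', n = %d\n", x$model_name, x$n))
  cat(sprintf("  observed mortality  %.1f%% (95%% CI %.1f, %.1f); expected %.1f%%\n",
              x$observed_mortality_pct, x$wilson_ci_95[1], x$wilson_ci_95[2],
              x$expected_mortality_pct))
  cat(sprintf("  c index             %.3f (%.3f, %.3f)\n",
              x$c_index, x$c_index_ci_95[1], x$c_index_ci_95[2]))
  cat(sprintf("  Hosmer-Lemeshow     chi2 %.1f on %d df (P = %.3g)\n",
              x$hl_chi2, x$hl_df, x$hl_p))
  cat(sprintf("  Cox calibration     intercept %.2f (%.2f, %.2f), slope %.2f (%.2f, %.2f), chi2 %.1f (P = %.3g)\n",
              x$cox_intercept, x$cox_intercept_ci_95[1], x$cox_intercept_ci_95[2],
              x$cox_slope, x$cox_slope_ci_95[1], x$cox_slope_ci_95[2],
              x$cox_chi2, x$cox_p))
  cat(sprintf("  Brier %.3f  ss-R2 %.3f  Shapiro's R %.3f  entropy-R2 %.3f\n",
              x$brier, x$ss_r2, x$shapiro_r, x$entropy_r2))
  invisible(x)
}

#' Flatten a validation report to a one-row data frame
#' @param report a `validation_report`.
#' @return A one-row data frame (interval bounds expanded to two columns).
#' @export
report_to_row <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  data.frame(
    model = report$model_name, n = report$n,
    observed_deaths = report$observed_deaths,
    observed_pct = report$observed_mortality_pct,
    observed_lo = report$wilson_ci_95[1], observed_hi = report$wilson_ci_95[2],
    expected_pct = report$expected_mortality_pct,
    c_index = report$c_index,
    c_lo = report$c_index_ci_95[1], c_hi = report$c_index_ci_95[2],
    hl_chi2 = report$hl_chi2, hl_p = report$hl_p,
    cox_intercept = report$cox_intercept, cox_slope = report$cox_slope,
    cox_chi2 = report$cox_chi2, cox_p = report$cox_p,
    brier = report$brier, ss_r2 = report$ss_r2,
    shapiro_r = report$shapiro_r, entropy_r2 = report$entropy_r2,
    stringsAsFactors = FALSE
  )
}

#' Write / read a validation report as JSON
#' @param report a `validation_report`.
#' @param path file path.
#' @return `write_validation_report` returns `path` invisibly;
#'   `read_validation_report` returns the `validation_report`.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  out <- unclass(report)
  out$calibration_table <- as.data.frame(out$calibration_table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$calibration_table <- as.data.frame(raw$calibration_table)
  class(raw$calibration_table) <- c("calibration_table", "data.frame")
  class(raw) <- "validation_report"
  raw
}
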