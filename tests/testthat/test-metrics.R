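# Discrimination, calibration and accuracy statistics, each checked
# against an independent naive oracle or a closed form.

test_that("c index handles separation, ties and matches pair enumeration", {
  expect_equal(c_index(ps_of(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)))$value, 1)
  expect_equal(c_index(ps_of(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)))$value, 0.5)
  # 6-record set with one tie, frozen from exhaustive pair counting:
  # deaths at (.7, .5, .3), survivors at (.5, .2, .1); pairs won 7, tied 1
  ps <- ps_of(c(0.7, 0.5, 0.3, 0.5, 0.2, 0.1), c(1, 1, 1, 0, 0, 0))
  expect_equal(c_index(ps)$value, 7.5 / 9)
  expect_error(c_index(ps_of(c(0.2, 0.3), c(1, 1))), "death and one survivor")
})

test_that("c index equals the all-pairs oracle on random sets with ties", {
  set.seed(101)
  for (i in 1:100) {
    ps <- random_ps(sample(10:60, 1), tie_levels = sample(c(NA, 4, 8), 1))
    expect_equal(c_index(ps)$value,
                 oracle_c_index(ps$predicted_risk, ps$outcome))
  }
})

test_that("c index is invariant under strictly monotone transforms", {
  set.seed(7)
  for (i in 1:20) {
    ps <- random_ps(80)
    f <- sample(list(function(x) x^3, function(x) plogis(5 * x),
                     function(x) exp(x) / 4), 1)[[1]]
    ps2 <- ps_of(f(ps$predicted_risk), ps$outcome)
    expect_equal(c_index(ps2)$value, c_index(ps)$value)
  }
})

test_that("DeLong self-comparison and antisymmetry", {
  set.seed(11)
  ps <- random_ps(150)
  self <- delong_test(ps, ps)
  expect_equal(self$difference, 0)
  expect_equal(self$variance, 0)
  expect_equal(self$p_two_sided, 1)
  # monotone transform: identical ranks, difference exactly 0
  ps2 <- ps_of(ps$predicted_risk^2, ps$outcome)
  expect_equal(delong_test(ps, ps2)$difference, 0)
  # antisymmetry of z under swapping models
  ps3 <- ps_of(plogis(qlogis(ps$predicted_risk) + rnorm(150, 0, 1)),
               ps$outcome)
  ab <- delong_test(ps, ps3)
  ba <- delong_test(ps3, ps)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_two_sided, ba$p_two_sided)
})

test_that("DeLong variance agrees with a paired bootstrap", {
  set.seed(12)
  n <- 200
  lo <- rnorm(n, -0.8, 1.5)
  y <- rbinom(n, 1, plogis(lo))
  if (sum(y) %in% c(0, n)) stop("degenerate draw")
  ps_a <- ps_of(plogis(lo), y, "a")
  ps_b <- ps_of(plogis(lo + rnorm(n, 0, 1.2)), y, "b")
  dl <- delong_test(ps_a, ps_b)
  boot <- replicate(10000, {
    idx <- sample.int(n, replace = TRUE)
    yb <- y[idx]
    if (sum(yb) %in% c(0, n)) return(NA_real_)
    oracle_fast <- function(p) {
      r <- rank(p)
      m <- sum(yb)
      (sum(r[yb == 1]) - m * (m + 1) / 2) / (m * (n - m))
    }
    oracle_fast(ps_a$predicted_risk[idx]) - oracle_fast(ps_b$predicted_risk[idx])
  })
  expect_lt(abs(dl$variance - var(boot, na.rm = TRUE)) / dl$variance, 0.15)
})

test_that("Hosmer-Lemeshow matches the 3-group hand computation", {
  # 100 records per group at constant risks 0.1 / 0.2 / 0.3 with observed
  # deaths 12 / 18 / 33; hand-summed chi2 = 4/9 + 1/4 + 3/7
  risk <- rep(c(0.1, 0.2, 0.3), each = 100)
  outcome <- unlist(mapply(function(o, n) c(rep(1, o), rep(0, n - o)),
                           c(12, 18, 33), c(100, 100, 100), SIMPLIFY = FALSE))
  hl <- hosmer_lemeshow(ps_of(risk, outcome), n_groups = 3)
  expect_equal(hl$chi2, 4 / 9 + 1 / 4 + 3 / 7)
  expect_equal(hl$df, 3)
  expect_equal(hl$table$n, rep(100L, 3))
  expect_equal(hl$table$observed, c(12L, 18L, 33L))
  expect_equal(hl$table$expected, c(10, 20, 30))
})

test_that("Hosmer-Lemeshow is zero for exact calibration and df equals groups", {
  # deterministic outcomes equal to expected counts within constant groups
  risk <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  outcome <- unlist(lapply(seq(0.05, 0.95, by = 0.1),
                           function(p) c(rep(1, round(20 * p)),
                                         rep(0, 20 - round(20 * p)))))
  hl <- hosmer_lemeshow(ps_of(risk, outcome), n_groups = 10)
  expect_equal(hl$table$observed, hl$table$expected)
  expect_equal(hl$chi2, 0)
  expect_equal(hl$p, 1)
  expect_equal(hl$df, 10)
})

test_that("calibration groups partition the cohort with near-equal sizes", {
  set.seed(21)
  ps <- random_ps(237)  # tie-free risks
  tab <- calibration_groups(ps, 10)
  expect_s3_class(tab, "calibration_table")
  expect_equal(sum(tab$n), 237L)
  expect_lte(diff(range(tab$n)), 1L)
  expect_equal(sum(tab$expected), sum(ps$predicted_risk))
  expect_equal(sum(tab$observed), sum(ps$outcome))
  expect_true(all(diff(tab$mean_risk) > 0))
  # tied predictions stay in one group
  ps2 <- ps_of(rep(c(0.2, 0.5, 0.8), c(30, 40, 30)),
               rbinom(100, 1, 0.3))
  tab2 <- calibration_groups(ps2, 10)
  expect_equal(sort(tab2$n[tab2$n > 0]), sort(c(30L, 40L, 30L)))
})

test_that("Cox calibration recovers truth and satisfies the df-2 identity", {
  set.seed(31)
  n <- 20000
  lo <- rnorm(n, -0.9, 1.6)
  y <- rbinom(n, 1, plogis(lo))
  ps <- ps_of(plogis(lo), y)
  cox <- cox_calibration(ps)
  expect_gt(cox$intercept, cox$intercept_ci_95[1] - 1e-9)
  expect_true(cox$intercept_ci_95[1] < 0.1 && cox$intercept_ci_95[2] > -0.1)
  expect_true(cox$slope_ci_95[1] < 1.1 && cox$slope_ci_95[2] > 0.9)
  expect_equal(cox$df, 2)
  expect_gte(cox$chi2, 0)
  expect_equal(cox$p, exp(-cox$chi2 / 2), tolerance = 1e-12)
})

test_that("Cox calibration inverts a linear log-odds distortion", {
  set.seed(32)
  n <- 50000
  lo_surv <- rnorm(n, 0.9, 1.6)           # survival log odds
  y_surv <- rbinom(n, 1, plogis(lo_surv))
  cc <- 0.4; d <- 1.25
  lo_surv_dist <- cc + d * lo_surv        # reported (distorted) predictions
  ps <- prediction_set(1:n, 1L - y_surv, log_odds = -lo_surv_dist)
  cox <- cox_calibration(ps)
  expect_equal(cox$intercept, -cc / d, tolerance = 0.05)
  expect_equal(cox$slope, 1 / d, tolerance = 0.03)
})

test_that("Brier, Shapiro's R and the scaled R2 statistics match hand arithmetic", {
  # 5-record hand vector
  p <- c(0.1, 0.4, 0.8, 0.3, 0.6)
  y <- c(0, 1, 1, 0, 0)
  ps <- ps_of(p, y)
  expect_equal(brier_score(ps),
               mean(c(0.1, 0.6, 0.2, 0.3, 0.6)^2))
  p_bar <- 0.4
  expect_equal(ss_r2(ps), 1 - brier_score(ps) / (p_bar * (1 - p_bar)))
  # 4-record geometric-mean hand vector
  ps4 <- ps_of(c(0.2, 0.7, 0.5, 0.9), c(0, 1, 0, 1))
  expect_equal(shapiro_r(ps4), (0.8 * 0.7 * 0.5 * 0.9)^(1 / 4))
  # perfect and null predictors
  perfect <- ps_of(c(0.999999999, 1e-9), c(1, 0))
  expect_equal(brier_score(perfect), 0, tolerance = 1e-12)
  expect_equal(ss_r2(perfect), 1, tolerance = 1e-7)
  expect_equal(shapiro_r(perfect), 1, tolerance = 1e-7)
  null_ps <- ps_of(rep(0.4, 10), c(rep(1, 4), rep(0, 6)))
  expect_equal(ss_r2(null_ps), 0)
  expect_equal(entropy_r2(null_ps), 0)
})

test_that("scaled R2 statistics never exceed 1", {
  set.seed(41)
  for (i in 1:25) {
    ps <- random_ps(60)
    expect_lte(ss_r2(ps), 1)
    expect_lte(entropy_r2(ps), 1)
    expect_gt(shapiro_r(ps), 0)
    expect_lte(shapiro_r(ps), 1)
  }
})

test_that("wilson_ci matches the root-finding oracle and brackets k/n", {
  set.seed(51)
  grid <- expand.grid(k_frac = c(0, 0.01, 0.1, 0.3, 0.5, 0.9, 1),
                      n = c(1, 10, 97, 1000, 23269))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    k <- round(grid$k_frac[i] * n)
    w <- wilson_ci(k, n)
    expect_equal(unname(w), oracle_wilson(k, n), tolerance = 1e-9)
    expect_true(w[1] >= 0 && w[2] <= 1)
    expect_true(w[1] <= k / n + 1e-12 && w[2] >= k / n - 1e-12)
  }
  expect_equal(unname(wilson_ci(0, 50)[1]), 0)
  expect_error(wilson_ci(3, 0), "n must")
  expect_error(wilson_ci(5, 3), "0 <= k <= n")
})

test_that("wilson interval width decreases with n at fixed k/n", {
  widths <- vapply(c(10, 100, 1000, 10000), function(n) {
    diff(unname(wilson_ci(round(0.3 * n), n)))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("ROC points are monotone and trapezoid area equals the c index", {
  set.seed(61)
  for (i in 1:50) {
    ps <- random_ps(sample(20:80, 1), tie_levels = sample(c(NA, 6), 1))
    roc <- roc_points(ps)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$tpr[nrow(roc)], 1)
    area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    expect_equal(area, c_index(ps)$value)
  }
  sep <- roc_points(ps_of(c(0.9, 0.8, 0.1), c(1, 1, 0)))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
})

test_that("c index agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(71)
  ps <- random_ps(300, tie_levels = 12)
  ref <- pROC::roc(ps$outcome, ps$predicted_risk, quiet = TRUE,
                   direction = "<")
  expect_equal(c_index(ps)$value, as.numeric(pROC::auc(ref)))
  v <- as.numeric(pROC::var(ref))
  expect_equal(c_index(ps)$se^2, v, tolerance = 1e-9)
})

test_that("validate assembles a coherent report that round-trips as JSON", {
  set.seed(81)
  sim <- generate_cohort(generator_config(n = 4000, seed = 81))
  rep <- validate(sim$preds_true)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$n, 4000L)
  expect_equal(rep$observed_mortality_pct, 100 * mean(sim$preds_true$outcome))
  expect_equal(rep$expected_mortality_pct,
               100 * mean(sim$preds_true$predicted_risk))
  # well calibrated by construction: observed close to expected
  expect_lt(abs(rep$observed_mortality_pct - rep$expected_mortality_pct), 3)
  expect_true(rep$wilson_ci_95[1] < rep$observed_mortality_pct &&
                rep$observed_mortality_pct < rep$wilson_ci_95[2])
  expect_true(rep$c_index >= 0 && rep$c_index <= 1)
  expect_gte(rep$hl_chi2, 0)
  expect_true(rep$shapiro_r > 0 && rep$shapiro_r <= 1)
  path <- tempfile(fileext = ".json")
  write_validation_report(rep, path)
  back <- read_validation_report(path)
  for (f in c("n", "c_index", "hl_chi2", "cox_slope", "brier", "ss_r2",
              "shapiro_r", "entropy_r2", "wilson_ci_95")) {
    expect_equal(back[[f]], rep[[f]], tolerance = 1e-12)
  }
  expect_equal(as.data.frame(back$calibration_table),
               as.data.frame(rep$calibration_table), tolerance = 1e-12)
})

test_that("perfect predictions give the degenerate report values", {
  y <- c(rep(1, 5), rep(0, 5))
  ps <- ps_of(ifelse(y == 1, 1 - 1e-9, 1e-9), y)
  expect_equal(c_index(ps)$value, 1)
  expect_equal(brier_score(ps), 0, tolerance = 1e-15)
  expect_equal(hosmer_lemeshow(ps)$chi2, 0, tolerance = 1e-4)
})
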