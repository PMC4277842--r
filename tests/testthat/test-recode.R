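# Harmonisation layer: location recoding, sedation assumption, regression
# imputation and hierarchical diagnosis mapping.

test_that("location recoding follows the indirect-admission rules", {
  expect_equal(recode_location("imaging", NA, "v0"), "emergency_department")
  expect_equal(recode_location("recovery", NA, "v0"), "general_ward")
  expect_equal(recode_location("general_ward", NA, "v0"), "general_ward")
  # recorded previous location wins over the assumption
  expect_equal(recode_location("imaging", "theatre", "v203"), "theatre")
  expect_equal(recode_location("recovery", "emergency_department", "v203"),
               "emergency_department")
  # vectorised
  expect_equal(
    recode_location(c("imaging", "recovery", "theatre"),
                    c(NA, NA, NA)),
    c("emergency_department", "general_ward", "theatre"))
  expect_error(recode_location("space_station"), "space_station")
  expect_error(recode_location("imaging", "space_station"), "space_station")
})

test_that("location recoding is idempotent", {
  set.seed(2)
  locs <- sample(c("imaging", "recovery", "general_ward", "theatre",
                   "emergency_department"), 50, TRUE)
  prev <- sample(c(NA, "general_ward", "emergency_department"), 50, TRUE)
  once <- recode_location(locs, prev)
  expect_equal(recode_location(once, prev), once)
})

test_that("sedation is assumed exactly when no GCS was recorded", {
  expect_equal(assume_sedation(NA), "sedated")
  expect_equal(assume_sedation(15L), "not_sedated")
  expect_equal(assume_sedation(3L), "not_sedated")  # presence, not value
  expect_equal(assume_sedation(c(NA, 7L, NA)),
               c("sedated", "not_sedated", "sedated"))
  expect_error(assume_sedation(2L), "3-15")
  expect_error(assume_sedation(16L), "3-15")
})

test_that("imputation model recovers a noiseless linear rule exactly", {
  set.seed(3)
  n <- 200
  tr <- data.frame(
    highest_sbp = runif(n, 100, 200),
    paired_dbp_at_highest = runif(n, 40, 100),
    lowest_dbp = runif(n, 30, 80),
    paired_sbp_at_lowest = runif(n, 70, 150)
  )
  tr$lowest_sbp <- 5 + 0.3 * tr$highest_sbp + 0.1 * tr$paired_dbp_at_highest +
    0.5 * tr$lowest_dbp + 0.2 * tr$paired_sbp_at_lowest
  m <- fit_imputation_model(tr, "lowest_sbp")
  expect_equal(unname(m$coefficients), c(5, 0.3, 0.1, 0.5, 0.2),
               tolerance = 1e-8)
  expect_equal(m$fit_n, n)
  expect_equal(m$residual_sd, 0, tolerance = 1e-7)
})

test_that("imputation coefficients land within 3 SE of truth under noise", {
  set.seed(4)
  n <- 10000
  tr <- data.frame(ph_at_lowest_pao2 = rnorm(n, 7.35, 0.1))
  truth <- c(0.9, 0.87)
  tr$lowest_ph <- truth[1] + truth[2] * tr$ph_at_lowest_pao2 + rnorm(n, 0, 0.05)
  m <- fit_imputation_model(tr, "lowest_ph")
  ref <- summary(lm(lowest_ph ~ ph_at_lowest_pao2, tr))$coefficients
  expect_true(all(abs(m$coefficients - truth) <= 3 * ref[, "Std. Error"]))
  expect_equal(unname(m$coefficients), unname(ref[, "Estimate"]))
})

test_that("degenerate imputation designs are rejected", {
  tr <- data.frame(ph_at_lowest_pao2 = rep(7.3, 20), lowest_ph = rep(7.2, 20))
  expect_error(fit_imputation_model(tr, "lowest_ph"), "degenerate|collinear")
  expect_error(fit_imputation_model(tr[1:2, ], "lowest_ph"), "complete training rows")
  # constant target with varying predictor: zero slope, intercept = constant
  tr2 <- data.frame(ph_at_lowest_pao2 = seq(7.0, 7.6, length.out = 30),
                    lowest_ph = 7.25)
  m <- fit_imputation_model(tr2, "lowest_ph")
  expect_equal(unname(m$coefficients), c(7.25, 0), tolerance = 1e-10)
})

test_that("imputed values equal the design-matrix product and are clamped", {
  set.seed(5)
  n <- 100
  tr <- data.frame(
    highest_sbp = runif(n, 100, 200),
    paired_dbp_at_highest = runif(n, 40, 100),
    lowest_dbp = runif(n, 30, 80),
    paired_sbp_at_lowest = runif(n, 70, 150)
  )
  tr$lowest_sbp <- 10 + 0.25 * tr$highest_sbp + 0.6 * tr$lowest_dbp +
    rnorm(n, 0, 5)
  m <- fit_imputation_model(tr, "lowest_sbp")
  new <- tr[sample(n, 100, TRUE), names(tr) != "lowest_sbp"]
  got <- impute_extreme(new, m)
  oracle <- unname(drop(cbind(1, as.matrix(new[m$predictor_names])) %*%
                          m$coefficients))
  expect_equal(got, oracle, tolerance = 1e-12)
  # prediction at the training means equals the training target mean
  at_mean <- as.data.frame(as.list(colMeans(tr[m$predictor_names])))
  expect_equal(impute_extreme(at_mean, m), mean(tr$lowest_sbp))
  # clamping to the physiological range
  wild <- new[1, ]; wild$highest_sbp <- 1e5
  expect_equal(impute_extreme(wild, m), 300)
  expect_error(impute_extreme(new[, -1], m), "highest_sbp")
})

test_that("intercept-only style model gives every record the same value", {
  tr <- data.frame(ph_at_lowest_pao2 = rep(c(7.2, 7.4), 10), lowest_ph = 7.3)
  m <- fit_imputation_model(tr, "lowest_ph")
  got <- impute_extreme(data.frame(ph_at_lowest_pao2 = runif(25, 7, 7.6)), m)
  expect_equal(got, rep(7.3, 25), tolerance = 1e-9)
})

test_that("imputation model round-trips through JSON", {
  set.seed(6)
  tr <- data.frame(ph_at_lowest_pao2 = rnorm(50, 7.35, 0.1))
  tr$lowest_ph <- 0.5 + 0.9 * tr$ph_at_lowest_pao2 + rnorm(50, 0, 0.02)
  m <- fit_imputation_model(tr, "lowest_ph")
  path <- tempfile(fileext = ".json")
  write_imputation_model(m, path)
  back <- read_imputation_model(path)
  newd <- data.frame(ph_at_lowest_pao2 = rnorm(10, 7.3, 0.1))
  expect_equal(impute_extreme(newd, back), impute_extreme(newd, m))
})

test_that("hierarchical codes enforce nesting and report their resolution", {
  full <- hierarchical_code("nonsurgical", "respiratory", "lung",
                            "infection", "pneumonia")
  expect_equal(full$resolution, "condition")
  expect_equal(hierarchical_code("surgical", "gastrointestinal")$resolution,
               "system")
  expect_equal(hierarchical_code("nonsurgical", "trauma", "multiple")$resolution,
               "site")
  expect_equal(unmapped_code()$resolution, "unmapped")
  expect_equal(hierarchical_code("nonsurgical")$resolution, "unmapped")
  expect_error(hierarchical_code("nonsurgical", NA, "lung"), "nested")
  expect_error(hierarchical_code("weird", "respiratory"), "type_tier")
})

test_that("diagnosis mapping is a pure lookup with unmapped as a value", {
  tbl <- demo_mapping_table()
  hit <- map_diagnosis("src_pneumonia", tbl)
  expect_equal(hit$resolution, "condition")
  expect_equal(hit$condition_tier, "bacterial_pneumonia")
  expect_equal(map_diagnosis("src_renal_failure", tbl)$resolution, "system")
  expect_equal(map_diagnosis("no_such_token", tbl)$resolution, "unmapped")
  expect_equal(map_diagnosis("src_unmappable", tbl)$resolution, "unmapped")
  # purity: repeated lookups identical
  expect_identical(map_diagnosis("src_copd", tbl),
                   map_diagnosis("src_copd", tbl))
})

test_that("mapping coverage reproduces a published-style tier distribution", {
  # 423 tokens: 295 condition / 44 process / 37 site / 28 system / 19 unmapped
  mk <- function(depth, i) {
    tiers <- c("nonsurgical", paste0("sys", i %% 12), paste0("site", i),
               paste0("proc", i), paste0("cond", i))
    do.call(hierarchical_code, as.list(tiers[seq_len(depth)]))
  }
  counts <- c(condition = 295, process = 44, site = 37, system = 28)
  entries <- list()
  i <- 0
  for (d in c(5, 4, 3, 2)) {
    nm <- names(counts)[c(5, 4, 3, 2) == d]
    for (j in seq_len(counts[[nm]])) {
      i <- i + 1
      entries[[sprintf("tok%03d", i)]] <- mk(d, i)
    }
  }
  for (j in 1:19) {
    i <- i + 1
    entries[[sprintf("tok%03d", i)]] <- unmapped_code()
  }
  cov <- mapping_coverage(mapping_table(entries))
  expect_equal(sum(cov$count), 423L)
  expect_equal(cov$count[cov$resolution == "condition"], 295L)
  expect_equal(cov$pct[cov$resolution == "condition"], 70L)
  expect_equal(cov$pct[cov$resolution == "process"], 10L)
  expect_equal(cov$pct[cov$resolution == "site"], 9L)
  expect_equal(cov$pct[cov$resolution == "system"], 7L)
  expect_equal(cov$pct[cov$resolution == "unmapped"], 4L)
  expect_lte(abs(sum(cov$pct) - 100), 1)  # rounding only

  empty <- mapping_coverage(mapping_table(list()))
  expect_equal(sum(empty$count), 0L)
  one <- mapping_coverage(mapping_table(list(
    a = hierarchical_code("surgical", "s", "si", "p", "c"))))
  expect_equal(one$pct[one$resolution == "condition"], 100L)
})

test_that("mapping tables round-trip through JSON", {
  tbl <- demo_mapping_table()
  path <- tempfile(fileext = ".json")
  write_mapping_table(tbl, path)
  back <- read_mapping_table(path)
  expect_equal(names(back$entries), names(tbl$entries))
  for (nm in names(tbl$entries)) {
    expect_equal(back$entries[[nm]]$resolution, tbl$entries[[nm]]$resolution)
    expect_equal(unclass(back$entries[[nm]]), unclass(tbl$entries[[nm]]))
  }
  expect_error(mapping_table(list(hierarchical_code("surgical", "x"))),
               "named")
})
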