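# Seeded synthetic-cohort generator. Emulates the case mix of a large
# adult general critical-care population (age ~58 +/- 18, 56% male, two
# thirds non-surgical, right-skewed physiology score ~19.6 +/- 9.5, ~30%
# acute hospital mortality) so that every pipeline stage and statistic can
# be exercised without patient data. Also builds a fixed 29,626-record
# fixture reproducing a reference exclusion cascade count-for-count.

#' Demonstration risk-model specification
#'
#' A synthetic logistic risk model in the structure of modern critical-care
#' mortality models: additive effects of the physiology score, age,
#' surgical status and prior CPR on the log-odds of acute hospital death.
#' Its coefficients are the package's own demonstration values (calibrated
#' so the default synthetic case mix has ~29.7% mean risk and c index near
#' 0.85); they are not any published model's coefficients.
#'
#' @return A [model_spec()].
#' @export
demo_model_spec <- function() {
  model_spec(
    name = "synthetic_demo",
    intercept = -5.84,
    terms = list(
      term_continuous("physiology_score", 0.17),
      term_continuous("age", 0.027),
      term_categorical("surgical_status",
                       weights = c(elective_scheduled = -1.8,
                                   emergency_urgent = -0.5,
                                   nonsurgical = 0)),
      term_categorical("cpr_24h", weights = c("TRUE" = 0.8, "FALSE" = 0))
    )
  )
}

# Table-1-style exclusion-reason taxonomy used to label synthetic cohorts
# for the exclusion-impact simulation: category, fraction of all
# admissions, and acute hospital mortality within the category.
default_impact_categories <- function() {
  data.frame(
    category = c("apache_excluded", "low_risk", "other_team", "unspecified"),
    frac = c(445, 2305, 88, 761) / 29626,
    mortality = c(290 / 407, 174 / 2291, 35 / 88, 232 / 743),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-cohort generator configuration
#'
#' Defaults describe the emulated study conditions: cohort size 23,269
#' over three years, age truncated-normal 57.5 (SD 18.0) on [16, 100],
#' 56.1% male, surgical status 10.5 / 22.4 / 67.2% (elective / emergency /
#' non-surgical), physiology score gamma-distributed to mean 19.6 / SD 9.5
#' (right-skewed, median below the mean) rounded to integers in [0, 100],
#' and outcomes drawn from [demo_model_spec()] so the true predictions are
#' well calibrated by construction. The competitor's predictions are
#' degraded in two separable ways: a linear distortion of the survival
#' log-odds (`lodds' = c + d * lodds`, the classic underprediction
#' pattern of an uncalibrated legacy model) and, optionally, additive
#' Gaussian log-odds noise (`noise_sd`) representing genuine information
#' loss, which lowers the competitor's c index.
#'
#' @param n cohort size.
#' @param seed RNG seed.
#' @param year_weights proportions of admissions per year 2007-2009.
#' @param age_mean,age_sd age distribution (years), truncated at [16, 100].
#' @param male_frac proportion male.
#' @param surgical_fracs proportions for elective_scheduled /
#'   emergency_urgent / nonsurgical; must sum to 1.
#' @param score_mean,score_sd physiology-score distribution.
#' @param true_model [model_spec()] generating the outcome probabilities.
#' @param distortion length-2 numeric `c(c, d)` applied to the
#'   competitor's survival log-odds; `d` must be non-zero. Cox calibration
#'   on the distorted predictions recovers intercept `-c/d` and slope
#'   `1/d` (when `noise_sd = 0`).
#' @param noise_sd SD of the competitor's additive log-odds noise.
#' @param exclusion_fracs data frame `category` / `frac` / `mortality`
#'   defining the exclusion-reason taxonomy used to label records for
#'   [simulate_exclusion_impact()].
#' @return A `generator_config`.
#' @export
generator_config <- function(n = 23269, seed = 1,
                             year_weights = c(7396, 7994, 7879) / 23269,
                             age_mean = 57.5, age_sd = 18.0,
                             male_frac = 0.561,
                             surgical_fracs = c(2438, 5196, 15608) / 23242,
                             score_mean = 19.6, score_sd = 9.5,
                             true_model = demo_model_spec(),
                             distortion = c(c = 0.29, d = 1.10),
                             noise_sd = 1.0,
                             exclusion_fracs = default_impact_categories()) {
  stopifnot(n >= 1, length(year_weights) == 3, length(surgical_fracs) == 3)
  if (abs(sum(surgical_fracs) - 1) > 1e-6 || abs(sum(year_weights) - 1) > 1e-6) {
    stop("year_weights and surgical_fracs must each sum to 1")
  }
  if (any(c(year_weights, surgical_fracs, male_frac) < 0) || male_frac > 1) {
    stop("proportions must lie in [0, 1]")
  }
  if (length(distortion) != 2 || distortion[2] == 0) {
    stop("distortion must be c(c, d) with d != 0")
  }
  stopifnot(inherits(true_model, "model_spec"), noise_sd >= 0)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 year_weights = year_weights, age_mean = age_mean,
                 age_sd = age_sd, male_frac = male_frac,
                 surgical_fracs = surgical_fracs, score_mean = score_mean,
                 score_sd = score_sd, true_model = true_model,
                 distortion = unname(distortion), noise_sd = noise_sd,
                 exclusion_fracs = exclusion_fracs),
            class = "generator_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic cohort with paired prediction sets
#'
#' Draws a cohort from [generator_config()], computes the true-model risk
#' for every admission, draws the outcome from that risk (so the true
#' predictions are well calibrated by construction), and builds a second,
#' degraded prediction set for the synthetic competitor (log-odds noise
#' for information loss, then the linear survival-log-odds distortion).
#' Fully reproducible from the seed.
#'
#' @param cfg a `generator_config`.
#' @return List with `records` (cohort data frame, including an
#'   `impact_category` label column), `preds_true`, `preds_distorted`
#'   (both [prediction_set()]s) and `config`.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  years <- sample(c(2007L, 2008L, 2009L), n, TRUE, cfg$year_weights)
  age <- rtrunc_norm(n, cfg$age_mean, cfg$age_sd, 16, 100)
  sex <- ifelse(stats::runif(n) < cfg$male_frac, "male", "female")
  surgical <- sample(c("elective_scheduled", "emergency_urgent", "nonsurgical"),
                     n, TRUE, cfg$surgical_fracs)
  shape <- cfg$score_mean^2 / cfg$score_sd^2
  scale <- cfg$score_sd^2 / cfg$score_mean
  score <- clamp(round(stats::rgamma(n, shape = shape, scale = scale)), 0, 100)
  cpr <- stats::runif(n) < 0.05
  location <- sample(c("emergency_department", "general_ward", "theatre",
                       "imaging", "recovery", "other_hospital"),
                     n, TRUE, c(0.30, 0.25, 0.30, 0.04, 0.04, 0.07))
  version <- ifelse(years <= 2008L, "v0", "v203")
  prev <- ifelse(version == "v203" & location %in% c("imaging", "recovery"),
                 sample(c("emergency_department", "general_ward"), n, TRUE),
                 NA_character_)
  highest_sbp <- clamp(stats::rnorm(n, 150, 20), 80, 280)
  paired_dbp <- clamp(0.5 * highest_sbp + stats::rnorm(n, 8, 8), 20, highest_sbp)
  lowest_dbp <- clamp(stats::rnorm(n, 52, 12), 20, 120)
  paired_sbp <- lowest_dbp + abs(stats::rnorm(n, 35, 12))
  ph <- clamp(stats::rnorm(n, 7.35, 0.08), 6.8, 7.7)
  gcs <- ifelse(stats::runif(n) < 0.4, NA_integer_,
                pmin(3L + stats::rpois(n, 9L), 15L))
  apache <- clamp(round(0.8 * score + stats::rnorm(n, 3, 3)), 0, 71)

  records <- data.frame(
    admission_id = sprintf("adm%07d", seq_len(n)),
    unit_id = sprintf("unit%02d", sample(1:24, n, TRUE)),
    year = years, age = age, sex = sex, surgical_status = surgical,
    location_prior = location, previous_location = prev,
    dataset_version = version, cpr_24h = cpr,
    highest_sbp = highest_sbp, paired_dbp_at_highest = paired_dbp,
    lowest_dbp = lowest_dbp, paired_sbp_at_lowest = paired_sbp,
    ph_at_lowest_pao2 = ph, gcs_lowest = gcs,
    physiology_score = as.integer(score), apache_score = as.integer(apache),
    diagnosis_code = sample(names(demo_mapping_table()$entries)[1:10], n, TRUE),
    exclude_from_scoring = FALSE, exclude_reason = NA_character_,
    is_readmission = FALSE,
    hospital_mortality = NA_character_,
    stringsAsFactors = FALSE
  )

  lo_true <- {
    base <- rep(cfg$true_model$intercept, n)
    for (tm in cfg$true_model$terms) base <- base + term_contribution(tm, records)
    clamp_log_odds(base)
  }
  risk_true <- inv_logit(lo_true)
  died <- stats::runif(n) < risk_true
  records$hospital_mortality <- ifelse(died, "died", "survived")
  records$impact_category <- assign_impact_categories(died, cfg$exclusion_fracs)

  preds_true <- prediction_set(records$admission_id, as.integer(died),
                               log_odds = lo_true,
                               model_name = cfg$true_model$name)
  # competitor: information loss (noise), then linear miscalibration of
  # the survival log-odds
  lo_surv <- -(lo_true + stats::rnorm(n, 0, cfg$noise_sd))
  lo_surv_dist <- cfg$distortion[1] + cfg$distortion[2] * lo_surv
  preds_distorted <- prediction_set(records$admission_id, as.integer(died),
                                    log_odds = -lo_surv_dist,
                                    model_name = "synthetic_competitor")
  list(records = records, preds_true = preds_true,
       preds_distorted = preds_distorted, config = cfg)
}

# Label records with exclusion-reason-like categories whose size and
# mortality match the taxonomy: members are drawn from deaths and
# survivors separately so each category hits its target death rate.
assign_impact_categories <- function(died, taxonomy) {
  n <- length(died)
  label <- rep("none", n)
  pool_d <- sample(which(died))
  pool_s <- sample(which(!died))
  for (i in seq_len(nrow(taxonomy))) {
    n_k <- round(taxonomy$frac[i] * n)
    d_k <- min(round(taxonomy$mortality[i] * n_k), length(pool_d))
    s_k <- min(n_k - d_k, length(pool_s))
    if (d_k > 0) {
      label[pool_d[seq_len(d_k)]] <- taxonomy$category[i]
      pool_d <- pool_d[-seq_len(d_k)]
    }
    if (s_k > 0) {
      label[pool_s[seq_len(s_k)]] <- taxonomy$category[i]
      pool_s <- pool_s[-seq_len(s_k)]
    }
  }
  label
}

#' Demonstration diagnosis mapping table
#'
#' A small synthetic mapping from source-system diagnosis tokens to
#' five-tier hierarchical codes, covering every resolution tier and one
#' declared-unmappable token. It stands in for a real source-to-hierarchy
#' mapping, which is a user-supplied input in practice.
#'
#' @return A [mapping_table()].
#' @export
demo_mapping_table <- function() {
  hc <- hierarchical_code
  entries <- list(
    src_pneumonia = hc("nonsurgical", "respiratory", "lung", "infection",
                        "bacterial_pneumonia"),
    src_copd = hc("nonsurgical", "respiratory", "lung", "obstruction",
                   "copd_exacerbation"),
    src_septic_shock = hc("nonsurgical", "cardiovascular", "whole_body",
                           "infection", "septic_shock"),
    src_cardiac_arrest = hc("nonsurgical", "cardiovascular", "heart",
                             "arrest", "cardiac_arrest"),
    src_gi_bleed = hc("nonsurgical", "gastrointestinal", "upper_gi",
                       "haemorrhage", "variceal_bleed"),
    src_laparotomy = hc("surgical", "gastrointestinal", "bowel",
                         "perforation", "perforated_viscus"),
    src_aaa_repair = hc("surgical", "cardiovascular", "aorta", "aneurysm",
                         "ruptured_aaa"),
    src_trauma = hc("nonsurgical", "trauma", "multiple"),
    src_overdose = hc("nonsurgical", "poisoning", "whole_body", "overdose"),
    src_renal_failure = hc("nonsurgical", "renal"),
    src_neuro_obs = hc("nonsurgical", "neurological", "brain"),
    src_unmappable = unmapped_code()
  )
  mapping_table(entries, provenance = "synthetic demonstration mapping")
}

# sub-reason structure of the flagged stratum in the exclusion fixture:
# category, sub-reason, records, records with a reported outcome, deaths
fixture_flag_breakdown <- function() {
  b <- rbind(
    c("apache_excluded", "death_within_4h",          231,  231, 231),
    c("apache_excluded", "missing_core_physiology",  103,  101,  33),
    c("apache_excluded", "age_under_16",              65,   30,   5),
    c("apache_excluded", "primary_burn_injury",       46,   45,  21),
    c("low_risk",        "high_dependency_patient", 1707, 1694, 116),
    c("low_risk",        "post_surgical_recovery",   598,  597,  58),
    c("other_team",      "awaiting_transfer",         45,   45,  22),
    c("other_team",      "under_another_team",        43,   43,  13),
    c("unspecified",     "unit_decision_not_to_score", 369, 360, 118),
    c("unspecified",     "other_unspecified",        298,  293,  87),
    c("unspecified",     "reason_not_documented",     94,   90,  27)
  )
  out <- data.frame(category = b[, 1], sub_reason = b[, 2],
                    n = as.integer(b[, 3]), with_outcome = as.integer(b[, 4]),
                    deaths = as.integer(b[, 5]), stringsAsFactors = FALSE)
  out
}

#' Generate the fixed exclusion-cascade fixture
#'
#' Builds, deterministically, a 29,626-record cohort whose exclusion
#' attributes reproduce a complete published-style cascade: 3,599
#' admissions flagged out of severity-of-illness scoring (with a full
#' sub-reason breakdown and 731 deaths among the 3,529 with a reported
#' outcome), 1,324 readmissions, 173 missing the hospital outcome, 869
#' missing location prior to admission (16) or primary diagnosis (864,
#' overlapping the location group by 11), 392 with an unmappable
#' diagnosis, and 23,269 clean analysis records (6,907 deaths; year split
#' 7,396 / 7,994 / 7,879 with 2,296 / 2,342 / 2,269 deaths). Use
#' [demo_mapping_table()] as the mapping when cascading: the unmappable
#' records carry its declared-unmappable token.
#'
#' @return Cohort data frame with a `fixture_stratum` label column and a
#'   `sub_reason` column for the flagged records.
#' @export
generate_exclusion_fixture <- function() {
  blank <- function(k, stratum) {
    data.frame(
      admission_id = character(k), unit_id = "unit01", year = 2008L,
      age = 60, sex = "male", surgical_status = "nonsurgical",
      location_prior = "emergency_department",
      previous_location = NA_character_, dataset_version = "v0",
      cpr_24h = FALSE, highest_sbp = 150, paired_dbp_at_highest = 80,
      lowest_dbp = 50, paired_sbp_at_lowest = 90, ph_at_lowest_pao2 = 7.35,
      gcs_lowest = NA_integer_, physiology_score = 20L,
      apache_score = 18L, diagnosis_code = "src_pneumonia",
      exclude_from_scoring = FALSE, exclude_reason = NA_character_,
      is_readmission = FALSE, hospital_mortality = "survived",
      fixture_stratum = stratum, sub_reason = NA_character_,
      stringsAsFactors = FALSE
    )
  }

  # flagged stratum with exact sub-reason outcome breakdown
  fb <- fixture_flag_breakdown()
  flagged <- blank(sum(fb$n), "flagged")
  flagged$exclude_from_scoring <- TRUE
  flagged$exclude_reason <- rep(fb$category, fb$n)
  flagged$sub_reason <- rep(fb$sub_reason, fb$n)
  outc <- unlist(lapply(seq_len(nrow(fb)), function(i) {
    c(rep("died", fb$deaths[i]),
      rep("survived", fb$with_outcome[i] - fb$deaths[i]),
      rep(NA_character_, fb$n[i] - fb$with_outcome[i]))
  }))
  flagged$hospital_mortality <- outc
  flagged$age[flagged$sub_reason == "age_under_16"] <- 12

  readm <- blank(1324, "readmission")
  readm$is_readmission <- TRUE

  miss_out <- blank(173, "missing_outcome")
  miss_out$hospital_mortality <- NA_character_

  # 16 missing location, 864 missing diagnosis, overlapping by 11 -> 869
  miss_fields <- blank(869, "missing_fields")
  miss_fields$location_prior[1:16] <- NA_character_
  miss_fields$diagnosis_code[6:869] <- NA_character_  # rows 6..16 overlap

  unmappable <- blank(392, "unmappable")
  unmappable$diagnosis_code <- "src_unmappable"

  # clean analysis records with the exact year and death split
  year_n <- c(`2007` = 7396L, `2008` = 7994L, `2009` = 7879L)
  year_d <- c(`2007` = 2296L, `2008` = 2342L, `2009` = 2269L)
  clean <- blank(sum(year_n), "clean")
  clean$year <- rep(c(2007L, 2008L, 2009L), year_n)
  clean$hospital_mortality <- unlist(lapply(names(year_n), function(y) {
    c(rep("died", year_d[y]), rep("survived", year_n[y] - year_d[y]))
  }))
  # deterministic, mildly varying fields so the cohort is usable downstream
  i <- seq_len(nrow(clean))
  clean$age <- 16 + (i * 7) %% 80
  clean$physiology_score <- as.integer((i * 13) %% 46)
  clean$apache_score <- as.integer((i * 11) %% 40)
  clean$sex <- ifelse(i %% 5 < 2, "female", "male")
  mappable <- setdiff(names(demo_mapping_table()$entries), "src_unmappable")
  clean$diagnosis_code <- mappable[(i %% length(mappable)) + 1]

  out <- rbind(flagged, readm, miss_out, miss_fields, unmappable, clean)
  out$admission_id <- sprintf("fix%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
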