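# Generic logistic risk-model engine. A model specification is an ordered
# list of terms (continuous, categorical, interaction) plus an intercept,
# under a fixed logistic link. Published critical-care models (the modern
# age / admission source / CPR / physiology score / diagnosis structure,
# or the legacy APACHE-II-style score-based layout) are expressed as
# coefficient tables supplied by the user; the engine carries no
# published coefficients.

MODEL_TRANSFORMS <- list(
  identity = function(x) x,
  log = function(x) log(x),
  log1p = function(x) log1p(x),
  sqrt = function(x) sqrt(x),
  square = function(x) x^2
)

#' Define a risk-model term
#'
#' @param field admission-schema field the term reads.
#' @param coef slope applied to the (transformed) field value.
#' @param transform one of `"identity"`, `"log"`, `"log1p"`, `"sqrt"`,
#'   `"square"`.
#' @param weights named numeric vector mapping categorical levels to
#'   additive weights.
#' @param reference optional reference level, implicitly weighted 0.
#' @param field_a,field_b fields entering an interaction; `field_a` is
#'   numeric. If `weights` is supplied the interaction multiplies
#'   `field_a` by the weight of `field_b`'s level; otherwise by
#'   `coef * field_b`.
#' @return A term definition (list) for [model_spec()].
#' @export
term_continuous <- function(field, coef, transform = "identity") {
  if (!transform %in% names(MODEL_TRANSFORMS)) {
    stop("unknown transform: ", transform)
  }
  list(type = "continuous", field = field, coef = coef, transform = transform)
}

#' @rdname term_continuous
#' @export
term_categorical <- function(field, weights, reference = NULL) {
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("categorical weights must be a fully named numeric vector")
  }
  list(type = "categorical", field = field,
       weights = as.list(weights), reference = reference)
}

#' @rdname term_continuous
#' @export
term_interaction <- function(field_a, field_b, coef = NULL, weights = NULL) {
  if (is.null(coef) == is.null(weights)) {
    stop("supply exactly one of `coef` (numeric x numeric) or `weights` ",
         "(numeric x categorical)")
  }
  list(type = "interaction", field_a = field_a, field_b = field_b,
       coef = coef, weights = if (!is.null(weights)) as.list(weights))
}

#' Construct a risk-model specification
#'
#' @param name model label.
#' @param intercept intercept on the log-odds (of death) scale.
#' @param terms list of terms built with [term_continuous()],
#'   [term_categorical()] or [term_interaction()].
#' @return A `model_spec` object.
#' @examples
#' spec <- model_spec("demo", intercept = -1,
#'                    terms = list(term_continuous("physiology_score", 0.1)))
#' @export
model_spec <- function(name, intercept = 0, terms = list()) {
  stopifnot(is.character(name), is_scalar_number(intercept), is.list(terms))
  for (tm in terms) {
    if (!is.list(tm) || !tm$type %in% c("continuous", "categorical", "interaction")) {
      stop("terms must be built with term_continuous/term_categorical/term_interaction")
    }
  }
  structure(list(name = name, intercept = intercept, terms = terms,
                 link = "logistic"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> '%s': intercept %.4g, %d terms, logistic link\n",
              x$name, x$intercept, length(x$terms)))
  invisible(x)
}

term_contribution <- function(tm, records) {
  get_field <- function(f, what) {
    if (!f %in% names(records)) {
      stop(sprintf("field '%s' required by %s term is missing", f, what))
    }
    v <- records[[f]]
    if (anyNA(v)) {
      stop(sprintf("field '%s' required by %s term has missing values", f, what))
    }
    v
  }
  switch(tm$type,
    continuous = {
      v <- get_field(tm$field, "continuous")
      tm$coef * MODEL_TRANSFORMS[[tm$transform %||% "identity"]](v)
    },
    categorical = {
      v <- as.character(get_field(tm$field, "categorical"))
      w <- unlist(tm$weights)
      hit <- match(v, names(w))
      out <- unname(w[hit])
      miss <- is.na(hit)
      if (any(miss)) {
        if (is.null(tm$reference)) {
          stop(sprintf("level '%s' of field '%s' has no weight and no reference default",
                       v[which(miss)[1]], tm$field))
        }
        out[miss & v == tm$reference] <- 0
        if (anyNA(out)) {
          stop(sprintf("level '%s' of field '%s' has no weight and no reference default",
                       v[which(is.na(out))[1]], tm$field))
        }
      }
      out
    },
    interaction = {
      a <- get_field(tm$field_a, "interaction")
      if (!is.null(tm$weights)) {
        b <- as.character(get_field(tm$field_b, "interaction"))
        w <- unlist(tm$weights)
        hit <- match(b, names(w))
        if (anyNA(hit)) {
          stop(sprintf("level '%s' of field '%s' has no interaction weight",
                       b[which(is.na(hit))[1]], tm$field_b))
        }
        a * unname(w[hit])
      } else {
        tm$coef * a * get_field(tm$field_b, "interaction")
      }
    },
    stop("unknown term type: ", tm$type)
  )
}

#' Predict risks from a model specification
#'
#' Computes, for each admission, the linear predictor (log-odds of death:
#' intercept plus the sum of term contributions) and the predicted risk
#' through the logistic link, with log-odds clamped at +/- 35.
#'
#' @param object a [model_spec()].
#' @param records cohort data frame (after recoding/imputation) containing
#'   every field the terms reference, plus `admission_id`; an
#'   `hospital_mortality` or `outcome` column supplies the observed
#'   outcome.
#' @param ... unused.
#' @return A [prediction_set()].
#' @export
predict.model_spec <- function(object, records, ...) {
  stopifnot(is.data.frame(records), "admission_id" %in% names(records))
  lo <- rep(object$intercept, nrow(records))
  for (tm in object$terms) lo <- lo + term_contribution(tm, records)
  outcome <- if ("outcome" %in% names(records)) {
    records$outcome
  } else if ("hospital_mortality" %in% names(records)) {
    as.integer(records$hospital_mortality == "died")
  } else {
    stop("records need an `outcome` (0/1) or `hospital_mortality` column")
  }
  prediction_set(records$admission_id, outcome, log_odds = lo,
                 model_name = object$name)
}

#' APACHE II total score
#'
#' Sums the Acute Physiology Score (0-60), age points and chronic health
#' points (0-5) into the 0-71 APACHE II score. The age categories are
#' fixed (<=44, 45-54, 55-64, 65-74, >=75); the point value for each
#' category (0-6) is supplied by the caller.
#'
#' @param aps Acute Physiology Score, integer 0-60 (vectorised).
#' @param age age in years at admission.
#' @param chronic_points chronic health points, integer 0-5.
#' @param age_point_table integer vector of length 5: points for the five
#'   age categories in increasing-age order.
#' @return Integer score(s) in 0-71.
#' @export
apache_ii_score <- function(aps, age, chronic_points,
                            age_point_table = c(0, 2, 3, 5, 6)) {
  if (length(age_point_table) != 5 ||
      any(age_point_table < 0 | age_point_table > 6)) {
    stop("age_point_table must give one value in 0-6 per the five age categories")
  }
  if (any(aps < 0 | aps > 60)) stop("aps out of range 0-60")
  if (any(chronic_points < 0 | chronic_points > 5)) {
    stop("chronic_points out of range 0-5")
  }
  cat_idx <- findInterval(age, c(-Inf, 45, 55, 65, 75))
  as.integer(aps + age_point_table[cat_idx] + chronic_points)
}

#' Diagnosis weight by longest hierarchical prefix
#'
#' Looks up the model weight for a hierarchical diagnosis code, falling
#' back from the deepest populated tier towards the body-system tier: the
#' weight of the deepest prefix present in the table is returned. A weight
#' is guaranteed to exist at the system tier, so any code resolved at
#' least to a body system can be weighted.
#'
#' @param code a [hierarchical_code()] with resolution at system tier or
#'   deeper.
#' @param weight_table named numeric vector; names are slash-joined tier
#'   prefixes, e.g. `"nonsurgical/respiratory"` or
#'   `"nonsurgical/respiratory/lung/infection/pneumonia"`.
#' @return The weight (numeric scalar).
#' @export
diagnosis_weight <- function(code, weight_table) {
  stopifnot(inherits(code, "hierarchical_code"))
  if (code$resolution == "unmapped") {
    stop("cannot weight an unmapped diagnosis; it should have been excluded")
  }
  tiers <- code_tiers(code)
  for (depth in rev(seq_along(tiers))) {
    key <- paste(tiers[seq_len(depth)], collapse = "/")
    if (key %in% names(weight_table)) return(unname(weight_table[key]))
  }
  stop("no weight found for code down to system tier: ",
       paste(tiers, collapse = "/"))
}

#' Write / read a model specification as JSON
#' @param spec a `model_spec`.
#' @param path file path.
#' @return `write_model_spec` returns `path` invisibly; `read_model_spec`
#'   the `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- lapply(raw$terms, function(tm) {
    tm[vapply(tm, is.null, logical(1))] <- NULL
    tm
  })
  model_spec(raw$name, intercept = as.numeric(raw$intercept), terms = terms)
}
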