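# Internal numerical helpers shared across modules.

# Log-odds are clamped at +/- 35 before exponentiation: risks become
# indistinguishable from 0/1 at double precision well inside that range,
# and the clamp prevents overflow in exp().
LOGODDS_CLAMP <- 35

# Probability clamp applied before any log(); keeps Shapiro's R and
# log-likelihoods finite without materially moving any statistic.
PROB_EPS <- 1e-10

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp_log_odds <- function(lo) clamp(lo, -LOGODDS_CLAMP, LOGODDS_CLAMP)

clamp_prob <- function(p) clamp(p, PROB_EPS, 1 - PROB_EPS)

inv_logit <- function(lo) stats::plogis(clamp_log_odds(lo))

logit <- function(p) stats::qlogis(clamp_prob(p))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
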