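# Independent brute-force oracles used to verify the package's
# implementations on small inputs. These deliberately use the naive
# definition of each statistic, not the package's algorithms.

# c index by exhaustive enumeration of (death, survivor) pairs,
# ties counted one half
oracle_c_index <- function(risk, outcome) {
  d <- risk[outcome == 1]
  s <- risk[outcome == 0]
  tot <- 0
  for (x in d) tot <- tot + sum(x > s) + 0.5 * sum(x == s)
  tot / (length(d) * length(s))
}

# Wilson bounds by numerical root-finding on the score equation
# (p_hat - p)^2 = z^2 p (1 - p) / n
oracle_wilson <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p_hat <- k / n
  g <- function(p) (p_hat - p)^2 - z^2 * p * (1 - p) / n
  # p_hat itself solves g at the boundary (k = 0 or k = n), so bracket
  # strictly inside the unit interval
  lower <- if (k == 0) 0 else {
    uniroot(g, c(1e-15, min(p_hat, 1 - 1e-15)), tol = 1e-12)$root
  }
  upper <- if (k == n) 1 else {
    uniroot(g, c(max(p_hat, 1e-15), 1 - 1e-15), tol = 1e-12)$root
  }
  c(lower, upper)
}

# quick prediction set from raw vectors
ps_of <- function(risk, outcome, name = "m") {
  prediction_set(seq_along(risk), outcome, predicted_risk = risk,
                 model_name = name)
}

# random prediction set with ties and both classes guaranteed
random_ps <- function(n, tie_levels = NULL) {
  risk <- if (is.null(tie_levels) || is.na(tie_levels)) runif(n) else {
    sample(seq(0.05, 0.95, length.out = tie_levels), n, replace = TRUE)
  }
  outcome <- rbinom(n, 1, risk)
  if (sum(outcome) == 0) outcome[which.max(risk)] <- 1L
  if (sum(outcome) == n) outcome[which.min(risk)] <- 0L
  ps_of(risk, outcome)
}
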