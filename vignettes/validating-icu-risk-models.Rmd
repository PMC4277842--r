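---
title: "Validating critical-care mortality risk models: methods and design choices"
author: "icuval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating critical-care mortality risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuval)
```

# The problem

A critical-care mortality model assigns each admission a probability of
death before acute hospital discharge, from predictors collected in the
first 24 hours in the unit. Using such a model on a population other than
the one it was developed in requires an external validation: the new
dataset rarely records exactly the fields the model expects, a
substantial fraction of admissions must be excluded for well-defined
reasons, and the model's performance must be quantified along three
distinct axes — discrimination (do deaths get higher risks than
survivors?), calibration (do predicted risks match observed
frequencies?) and overall accuracy (how close are predictions to
outcomes?). `icuval` packages that workflow: harmonisation, an auditable
exclusion cascade, a coefficient-table-driven logistic prediction engine,
and a from-scratch implementation of the standard validation statistics.

# The exclusion cascade

Admissions are removed in five fixed stages: (1) flagged out of
severity-of-illness scoring at source; (2) readmissions within the same
acute hospital stay (their outcomes are not independent); (3) missing the
hospital outcome; (4) missing age, location prior to admission, or
primary diagnosis; (5) a diagnosis that cannot be mapped onto the
hierarchical coding scheme. A record meeting several criteria is counted
only at the first stage that removes it, which makes the per-stage counts
and the retained total reconcile exactly (`removed + retained = in`,
always). Permuting the stages can redistribute the per-stage counts but
never changes the retained set, because the criteria are evaluable
independently per record; the test suite asserts this on permuted runs.

Readmission status is taken from an explicit flag rather than re-derived
by linking episodes: episode linkage rules are institution-specific and
out of scope. Unknown flag-reason categories are bucketed as
"unspecified" with a warning rather than rejected, since the reason
taxonomy is descriptive, not load-bearing.

The package ships a deterministic 29,626-record fixture
(`generate_exclusion_fixture()`) whose cascade removes
3,599 / 1,324 / 173 / 869 / 392 records, retaining 23,269 (78.5%). Two
details are worth recording. First, the stage-4 sub-counts (16 missing
location, 864 missing diagnosis) sum to 880, not 869: the fixture makes
the two groups overlap by 11 records, the unique overlap consistent with
a union count of 869 when no admissions are missing age. Second, the
flagged stratum carries a full sub-reason breakdown with per-sub-reason
outcome denominators smaller than the record counts (outcome is partially
missing among flagged admissions: 3,529 of 3,599 have one, of whom 731
died); the fixture reproduces these numerator/denominator pairs verbatim.

# Harmonisation

**Location prior to admission.** Admissions arriving from an imaging
department or from a recovery area used as overflow critical care are
weighted by wherever they were before that. When the previous location
was never recorded (legacy single-location records), the most common true
antecedents are assumed: emergency department for imaging, general ward
for recovery. The recoding is idempotent, so it can safely be applied to
already-clean data.

**Physiology extremes.** Some audits record only the highest systolic
pressure (with paired diastolic) and the lowest diastolic (with paired
systolic), not the lowest systolic pressure a score needs — and only the
pH from the gas with the lowest PaO2, not the lowest pH. Substituting the
most similar recorded value would bias severity downwards, so the package
fits OLS regressions of the target extreme on its recorded surrogates
(`fit_imputation_model()`) and predicts deterministically
(`impute_extreme()`). No imputation coefficients are bundled: they must
be fitted on reference data or supplied as JSON, because any constants we
invented would masquerade as a published equation. Whether the reference
equations used transformed or interaction terms is not knowable from
their published descriptions; plain linear terms are used. Predictions
are clamped to physiological ranges — systolic pressure to [0, 300] mmHg,
pH to [6.0, 8.0] — so an extrapolated regression can never push an
impossible value into scoring. The clamp bounds are our choice, selected
to be wide enough never to bind on plausible data.

**Sedation.** Where sedation was not recorded, an admission with no
lowest Glasgow Coma Score in the first 24 h is assumed sedated; any
recorded GCS, whatever its value, implies not sedated. The rule is driven
by presence, not value — a GCS of 3 still means "assessable".

**Diagnosis mapping.** Reasons for admission are coded in a five-tier
hierarchy: type (surgical/nonsurgical), body system, site, process,
condition. Tiers are strictly nested, a code's *resolution* is its
deepest populated tier, and a weight can be assigned from the system tier
downward by longest-prefix lookup (`diagnosis_weight()`). "Unmapped" is
modelled as a resolution value rather than an error so the exclusion
cascade can count it. Mapping tables are JSON with explicit tier fields —
five-level nesting is unambiguous there in a way flat delimited text is
not. A small synthetic demonstration table is bundled; real
source-to-hierarchy mappings are user inputs.

# The prediction engine

`model_spec()` describes a logistic model as an intercept plus an ordered
list of terms: continuous (field × coefficient, with optional named
transform), categorical (level → weight, with an optional zero-weight
reference level), and interaction (numeric × numeric with a coefficient,
or numeric × categorical with a per-level slope — the construction needed
for physiology-score × diagnosis interactions). The engine carries no
published coefficients: the coefficient sets of the models it is designed
to express are not in the public domain, so specifications are
user-supplied JSON, and the bundled `demo_model_spec()` is labelled as
the package's own synthetic demonstration. Log-odds are clamped at ±35
before the inverse logit — risks are indistinguishable from 0/1 at double
precision well inside that range, and the clamp removes overflow as a
failure mode. The APACHE II score helper hard-codes only the printed age
category boundaries (≤44, 45–54, 55–64, 65–74, ≥75); the point values per
category are arguments.

# The statistics

All statistics are implemented from first principles and each is tested
against an independent brute-force oracle (exhaustive pair enumeration,
hand-summed chi-squared, root-finding on the score equation, paired
bootstrap).

**c index / DeLong.** Computed via midranks in $O(n \log n)$; ties count
½. The variance uses DeLong's structural components
$V^{10}_i$ (per death) and $V^{01}_j$ (per survivor); the paired
two-model test uses the variance of the component differences. The
confidence interval is the symmetric normal interval value ± 1.96·SE,
truncated to [0, 1]. Two models are compared on the intersection of
admissions scored by both.

**Hosmer–Lemeshow.** Ten near-equal groups by predicted probability;
records with identical predictions stay in one group (deterministic and
order-independent, at the price of unequal groups; empty groups
contribute nothing). The statistic is referred to $\chi^2$ on *10* df,
not 8: in external validation no parameters are estimated on the
validation data, so the grouped statistic keeps one df per group.

**Cox calibration regression.** Observed survival regressed on predicted
survival log-odds by maximum likelihood (`stats::glm`). The joint test of
(intercept, slope) = (0, 1) is a likelihood-ratio $\chi^2$ against the
offset model on 2 df, which gives the exact identity
$p = e^{-\chi^2/2}$; a Wald version would also have 2 df but not that
closed form. Parameter intervals are Wald. Non-convergence and complete
separation raise errors rather than returning garbage.

**Accuracy.** Brier score and Shapiro's R (geometric mean of the
probability assigned to the realised outcome), each scaled against the
null model predicting the cohort death rate for everyone:
$R^2_{SS} = 1 - B/B_0$ and $R^2_{ent} = 1 - \ln R / \ln R_0$. Assigned
probabilities are clamped at $\varepsilon = 10^{-10}$ before any
logarithm; this keeps likelihoods finite without materially moving any
statistic.

**Wilson intervals.** Closed-form score intervals, clamped to [0, 1]
(the algebraic lower bound at $k=0$ is exactly 0 but floating-point
arithmetic can produce $-10^{-18}$).

# The synthetic generator

`generator_config()` defaults encode the emulated study conditions: a
23,269-admission cohort over three years (7,396 / 7,994 / 7,879), age
truncated-normal 57.5 (SD 18.0) on [16, 100], 56.1% male, surgical status
in the proportions 2,438 : 5,196 : 15,608 (the printed counts, which sum
to 23,242, are normalised — they undershoot the cohort N by 27,
presumably unclassified records), and a physiology score drawn from a
gamma distribution solved from mean 19.6 / SD 9.5 then rounded into
[0, 100] — the right skew reproduces a median (18) below the mean.
Outcomes are drawn from the demonstration model's own risks, so the true
prediction set is well calibrated *by construction* and its expected
mortality (~29.7%) matches observed up to binomial noise. The
demonstration coefficients (score 0.17, age 0.027, elective −1.8,
emergency −0.5, CPR 0.8, intercept −5.84) were chosen once so that the
default case mix yields ~29.7% mean risk, risk SD ≈ 0.26 and a c index
near 0.85 — the regime a well-discriminating modern ICU model operates
in.

The competitor's predictions are degraded in two deliberately separable
ways, because the two published failure modes of a legacy comparator are
distinct: (i) additive Gaussian log-odds noise (default SD 1.0),
representing genuine information loss, which lowers the c index (to
~0.80 at default settings) — a purely monotone distortion could never do
that; and (ii) a linear distortion of the survival log-odds,
$\ell' = c + d\,\ell$ with default $(c, d) = (0.29, 1.10)$, so that Cox
calibration regression on the distorted set recovers intercept
$-c/d \approx -0.26$ and slope $1/d \approx 0.91$ — the classic
"underpredicts risk, underpredicts variability" pattern. With the noise
switched off the distortion is exactly invertible and the c index is
exactly preserved (asserted in the tests); with noise on, the recovered
slope is additionally attenuated, so parameter-recovery checks use
noise-free configurations and discrimination checks use noisy ones.

Records are also labelled with an exclusion-reason-style taxonomy
(category sizes and within-category death rates matching a published
flagged-admission breakdown) to drive `simulate_exclusion_impact()`,
which re-estimates the c index, Brier score and observed/expected ratio
after randomly removing a stated fraction of each category.

What the generator does *not* emulate: unit-level clustering, seasonal
admission patterns, correlated missingness, or any real relationship
between the auxiliary physiology fields and the outcome model. Passing
tests therefore demonstrate the correctness of the statistical machinery
under a realistic marginal case mix, not the performance any particular
model would achieve on real admissions.

# Numerical and testing choices

- Quantile group ties: tied predictions share the group of their first
  sorted position; groups may be unequal but assignment is deterministic.
- The DeLong variance of a model against itself is exactly 0; the
  self-comparison returns difference 0 and p 1 rather than 0/0.
- Joint coverage of (intercept, slope) in the parameter-recovery tests is
  assessed by the 2-df likelihood-ratio confidence region (equivalently,
  the Cox chi-squared test not rejecting at α = 0.05). Requiring the two
  marginal 95% Wald intervals to cover simultaneously is not a 95% joint
  statement — its joint coverage is ≈ 89% — whereas the LR region is the
  canonical confidence region for a two-parameter hypothesis.
- Testing (intercept, slope) = (a, b) on predictions $x$ is implemented
  by testing (0, 1) on the affinely adjusted predictions $a + bx$, which
  is an exact reduction.
- Problem sizes: property tests run at n ≤ 60 against exhaustive
  oracles; the bootstrap cross-check uses n = 200 with 10,000 draws;
  parameter-recovery runs use 50 replicates of n = 50,000, the scale at
  which CIs are tight enough for coverage statements to be informative
  while a full suite run stays around a minute.

# Limitations

- The engine validates models; it does not recalibrate them, and no
  published coefficient set is bundled — results on real data require
  the genuine coefficient tables and mapping files as inputs.
- The Hosmer–Lemeshow df convention (10) is correct for external
  validation only; do not reuse these p-values for a model fitted on the
  same data.
- `simulate_exclusion_impact()` removes records at random within
  categories; if exclusions are informative *within* a category beyond
  its death rate, the simulation understates their impact.
- The c-index interval is the symmetric normal interval; near-perfect
  discrimination (c → 1) would warrant a logit-scale interval instead.
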