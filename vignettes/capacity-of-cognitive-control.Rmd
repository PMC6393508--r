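---
title: "Estimating the capacity of cognitive control and its latent structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the capacity of cognitive control and its latent structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogcap)
```

## The capacity model

The masked majority-function task (MFT-M) asks an observer to report the
majority direction of five briefly exposed arrows. Displays differ in
arrow congruency (5:0, 4:1, 3:2) and exposure time (ET of 0.25, 0.5, 1,
or 2 s), crossed into 12 design cells. The package models performance
under a grouping-search strategy: the observer repeatedly samples
$N_{maj} = 3$ of the 5 arrows until the sample is unanimous. The
per-attempt success probability is hypergeometric,

$$P_{group} = \frac{\binom{maj}{3} + \binom{min}{3}}{\binom{5}{3}},$$

giving 1, 0.4 and 0.1 for the three ratios. The expected number of
scanned arrows is $N = N_{maj} / P_{group}$, its $\log_2$ is the
condition's entropy in bits (1.58, 2.91, 4.91), and $\log_2(N/ET)$ is
the information rate the cell demands in bits per second. One detail
worth recording: the minimum rate over the design is
$\log_2(3/2) = 0.585$ bps, which prints as 0.58 at two decimals; reports
that state 0.59 have rounded the three-decimal value 0.585 upward a
second time.

A subject with capacity $C$ (bits/s) affords $k = 2^C \cdot ET / N_{maj}$
sampling attempts within the exposure. If any attempt succeeds the trial
terminates voluntarily and the response is correct with the baseline
probability $p_0$; otherwise the observer guesses at $p_{guess} = 0.5$:

$$E[\mathrm{acc}] = p_0 - (1 - P_{group})^{\,2^C ET / N_{maj}}\,(p_0 - p_{guess}).$$

`expected_accuracy()` evaluates this closed form; it is nondecreasing in
$C$ and $ET$ and bounded between $p_{guess}$ and $p_0$. The exponent is
real-valued; `0^0` is taken as 1 so fully congruent cells return $p_0$
for any capacity.

## Estimating C

`fit_ccc()` uses a two-stage estimator. The baseline $p_0$ is the
trial-weighted mean accuracy of the congruent (5:0) cells, pooled across
exposure times — the congruent cells are constant in $C$, so they carry
no other information about it. $C$ then maximizes the binomial
log-likelihood of the incongruent cell counts, with predicted accuracies
clamped to $[\epsilon, 1-\epsilon]$, $\epsilon = 10^{-6}$. "Optimal
likelihood" could also be read as least squares between observed and
predicted accuracies, so that objective is available via
`objective = "least_squares"`; on noiseless cells the two agree to well
under the sampling error of a 36-trial cell.

The search interval defaults to $C \in [0.1, 10]$ bps, comfortably
covering the 2–5 bps range typical of adult samples. Because the
likelihood flattens once predicted accuracies saturate, the optimizer
runs a 101-point grid pre-scan and then refines within the bracketing
interval. A fit is flagged `at_bound` when the optimum lands at either
end of the interval, and `converged = FALSE` when the data are
uninformative (all incongruent accuracies at or beyond the guessing or
ceiling levels).

Parameter recovery under the session layout (12 cells of 36 trials) is
part of the acceptance suite: for true $C \in \{2, 3, 3.82, 5\}$ with
$p_0 = 0.99$, the median absolute error over 200 simulated subjects per
level stays within 0.25 bps, and it shrinks as trials per cell grow.

## Battery scoring

* **Conflict effect (EC).** Flanker trials are cleaned by removing
  errors, then trimming RTs beyond 3 SD of their congruency condition's
  mean (mean and SD from correct trials, single pass — the rule is not
  iterated, since re-trimming is a different estimator). The score is
  reverse-coded, `mean RT(congruent) − mean RT(incongruent)`, so that
  *less negative = better control* and all battery correlations are
  positively oriented.
* **N-back indices.** Hardest-level minus 0-back accuracy: 2-back for
  the spatial task, 3-back for the verbal task, fixed per task rather
  than auto-detected.
* **Complex span.** All-or-nothing load: a trial contributes its full
  set size only when every element was recalled in serial order,
  normalized by the total element count.
* **Exclusion.** Subjects are removed when MFT-M valid responses fall
  below 95%, flanker accuracy (computed before trimming) below 90%,
  0-back accuracy in either N-back task below 90%, distractor accuracy
  in any span task below 85%, or US education below 15 years. All
  thresholds are strict, so a subject exactly at a threshold is kept,
  and removal is the union over rules (order-independent, idempotent).

## Correlation inference

Directional hypotheses are tested with one-tailed Pearson correlations
($t = r\sqrt{n-2}/\sqrt{1-r^2}$, upper tail). Each correlation carries a
default Jeffreys–Zellner–Siow Bayes factor computed by one-dimensional
quadrature over the $g$ prior; the two-sided default depends only on
$(|r|, n)$. In `correlation_table()` the Bayes factor is computed on the
correlation *rounded to two decimals*: published tables of this kind
show identical Bayes factors wherever rounded correlations coincide,
which identifies rounded $r$ as the Bayes factor's effective input. BF
above 100 renders as ">100". Evidence bands: >100 decisive, >3
substantial, <1/3 substantial evidence for the null, otherwise
insensitive, with boundary values assigned to the weaker category.

For comparing two dependent correlations sharing an outcome, both
Steiger's $Z_1^*$ and the Meng–Rosenthal–Rubin $z$ are implemented.
Steiger's variant is the default: on rounded published inputs it tracks
reported statistics of this design more closely (the Meng form runs
visibly lower when the two correlations differ greatly), and the two
agree in sign and ordering everywhere. The one-sided $p$ comes from the
normal upper tail.

## Latent-variable models

The four structural models are correlated-factor specifications over the
battery's manifest variables:

1. **IQ–CC–WM** — IQ over VCI/PRI/WMI/PSI, cognitive control over
   CCC/EC, working memory over both N-back indices and the three span
   scores, with free error covariances WMI–CCC and WMI–OSpan (df = 39).
2. **Gc–Gf–CC** — Gc is the single indicator VCI with its error
   variance fixed to 0, Gf over PRI/WMI/PSI (df = 7).
3. **Gc–Gf–WM** — as above with working memory (df = 25).
4. **CC–WM** — the two-factor model (df = 13).

Identification fixes every latent variance to 1 (all loadings free), so
latent covariances are correlations. The published degrees of freedom
and BIC values of this design are internally consistent only under this
flat correlated-factor parameterization — a hierarchical second-order
layer over four first-order factors yields q = 31 and df = 35 for model
1 rather than the reported 39 — and only when the error-covariance links
are free in model 1 alone. The BIC convention that reproduces the
published values exactly is $BIC = \chi^2 + q\ln n$; both facts are
verifiable from the fixtures (`battery_sem_models()`, `sem_df()`).

`fit_ml()` minimizes the Wishart discrepancy
$F_{ML} = \ln|\Sigma(\theta)| + tr(S\Sigma^{-1}) - \ln|S| - p$ with
analytic gradients under L-BFGS-B, error variances bounded at 0, five
jittered starts, and a gradient tolerance of $10^{-8}$. All the models
here are scale-free (each manifest has a free loading and a free error
variance), so the optimizer works on the correlation metric — the raw
manifest scales span five orders of magnitude (ms² versus proportions)
and would otherwise wreck the conditioning — and estimates are rescaled
back to the covariance metric afterwards; $\chi^2$ is unaffected.
$\chi^2 = (n-1)F_{ML}$ follows the classical Wishart convention. RMSEA,
TLI and CFI are computed against the analytic independence baseline
($\Sigma_b = \mathrm{diag}(S)$), with the usual cut-offs
($\chi^2/df < 2$, RMSEA < 0.06, TLI/CFI > 0.95) attached as verdicts.
BIC differences are banded as >2 positive, >6 strong, >10 very strong
evidence against the higher-BIC model.

The engine's oracle suite (saturated model at $\chi^2 = 0$; round-trip
$F_{ML} < 10^{-8}$ from covariances generated by known parameters; a
path-tracing cross-check of $\Sigma(\theta)$ on a toy model) runs in the
tests, and latent-correlation recovery is measured on cohorts sampled
from the model-1 population (correlations 0.84 / 0.87 / 0.96) at
n = 500 over 50 replicates, with median absolute error within 0.08.

## The cohort simulator

`simulate_cohort()` exists so the pipeline is exercisable end-to-end and
recovery is measurable; only the MFT-M generator embodies a cognitive
model (the same voluntary/forced-termination process as the closed
form, with the real-valued attempt exponent; an integer-attempt mode
supports brute-force cross-checks). The flanker, N-back and span
generators are declared plumbing with simple parametric forms: shifted
truncated-normal RTs, binomial per-level accuracies with the battery's
trial counts (80 per spatial level, 18 per verbal level), and
all-or-nothing recall with per-element probability logistic in set size
($q(s) = \mathrm{logit}^{-1}(a - 0.25(s-2))$, trial success $q^s$).

Defaults are set once to the study's conditions: 88 subjects; latent
correlations 0.84/0.87/0.96; 432 MFT-M trials and 288 flanker trials
per subject; capacity mapped as $3.82 + 0.62\,s$ bps and conflict cost
as $144.06 - 41.65\,s$ ms from the measure-level latent score $s$; span
intercepts 2.9/2.6/1.9 chosen so expected span scores sit near
0.56/0.44/0.45. One global seed fans out to fixed per-task substreams,
so adding a task leaves existing streams untouched, and equal seeds give
byte-identical cohorts.

What the simulator does **not** emulate: RT dynamics within the MFT-M,
serial-position or strategy effects in recall, practice and fatigue,
demographic structure, and any misfit between the factor model and the
measure-level nonlinearities beyond what the parameter maps induce.
Passing recovery tests therefore certify the estimators against their
own generating assumptions, not against the full complexity of real
data.

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(default_population(n_subjects = 60, seed = 11))
result <- run_full_analysis(cohort)
result$summary
result$sem_index_table
print(result$correlations)
```

## Problem sizes and limitations

The test suite runs the recovery studies at the sizes quoted above (200
subjects per capacity level; 50 replicate cohorts of 500 for the latent
models; about $10^5$ replicates per cell for the Monte-Carlo agreement
check), which keeps the default run within a couple of minutes while
leaving the Monte-Carlo error well below the tolerance being asserted.

Known limitations: the capacity model commits to the grouping-search
strategy and the five-arrow design; no response-time model for the
MFT-M; no partial-credit span scoring; no robust or missing-data SEM
estimators, standard errors, or modification indices (the two error
links are fixed model features); and published fit statistics that
depend on an unreleased raw covariance matrix can be checked only for
structural quantities (df, index formulas, BIC convention), not
reproduced numerically.
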