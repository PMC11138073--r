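---
title: "A quasi-Markov cost-utility model for family therapy after adolescent self-harm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quasi-Markov cost-utility model for family therapy after adolescent self-harm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qmcea` implements a long-term cost-utility analysis comparing manualised
systemic family therapy (FT, delivered on top of treatment as usual) with
treatment as usual alone (TAU) for adolescents aged 11–17 referred to mental
health services after repeated self-harm. The evaluation takes an NHS and
Personal Social Services costing perspective, runs over a 5-year horizon in
ten 6-month cycles, and discounts future costs and QALYs at 3.5% a year.
This vignette is the package's own account of the model, its assumptions,
and the design decisions behind the implementation.

## The model

### Three states, no transition matrix

Each patient occupies one of three mutually exclusive states per cycle:

* **RSH** — repeated self-harm: at least one self-harm hospitalisation
  during the 6-month cycle (base case). A secondary analysis instead uses
  *any* hospitalisation, on the argument that hospitalisation in this young
  cohort is rare and, when observed, very likely self-harm-related.
* **non-RSH** — no qualifying hospitalisation in the cycle.
* **Death** — absorbing.

Unlike a conventional Markov cohort model, state membership is *not*
propagated through a transition matrix. Because hospital records cover the
entire horizon, the per-cycle probability of the state event can be
estimated directly: a GEE logistic regression of the event indicator on
baseline covariates (age group, gender, index hospitalisation cause,
hospital-referred flag), cycle dummies, and a saturated arm-by-cycle
interaction, clustered on patient. Occupancy is then

$$\pi_{RSH}(c) = P(\text{event at } c \mid \text{alive})\,(1 - \pi_{death}(c)),
\qquad \pi_{nonRSH}(c) = 1 - \pi_{RSH}(c) - \pi_{death}(c),$$

with $\pi_{death}(c)$ the Kaplan–Meier cumulative death probability at the
end of cycle $c$. Treating the event probability as conditional on being
alive and scaling by survival is a deliberate simplification: with only two
deaths in roughly 800 patients, joint modelling of death and self-harm
would estimate nothing. Rows of the occupancy table sum to one by
construction and the engine validates this to $10^{-12}$.

### The regression suite

Every quantity the engine consumes is a fitted "average participant"
prediction (covariate means on the linear predictor scale) from one of ten
models, all clustered on patient:

| model | outcome | family/link |
|---|---|---|
| 1 | P(self-harm hospitalisation) | binomial, logit |
| 2 | P(any hospitalisation) | binomial, logit |
| 3 | cost of SH hospitalisation, given one | gamma, log |
| 4 | cost of any hospitalisation, given one | gamma, log |
| 5 | P(non-SH hospitalisation \| SH status) | binomial, logit |
| 6 | cost of non-SH hospitalisation, given one | gamma, log |
| 7 | P(non-hospital cost occurs \| state) | binomial, logit |
| 8 | non-hospital cost, given one | gamma, log |
| 9 | utility \| state | gaussian, identity |
| 10 | death | Kaplan–Meier |

Models 7–9 use trial-collected data (questionnaires at months 0–18, i.e.
cycles 0–2 only). Beyond the trial window there is no direct observation of
non-hospital costs or utilities, so the package extrapolates them
*indirectly*: the final trial cycle's fitted relationship between the state
event and occurrence/magnitude/utility is carried forward, and only the
(directly observed) hospitalisation probabilities move. A one-way analysis
zeroes post-trial non-hospital costs instead.

Expected per-cycle cost in the base case composes as

$$P_{SH} E[c_{SH}] + \left[P_{SH} P(nonSH\mid SH) + (1-P_{SH})
P(nonSH \mid noSH)\right] E[c_{nonSH}] + \text{non-hospital expectation},$$

all scaled by $1 - \pi_{death}$; expected utility is
$\pi_{RSH} u_{SH} + \pi_{nonRSH} u_{noSH}$, and each cycle contributes
utility × 0.5 years of QALYs. Death contributes zero cost and zero utility
(standard convention; the source is silent).

### GEE fitting

The fitter solves the estimating equations by Fisher scoring with either
independence (default) or exchangeable working correlation, and reports the
cluster-robust sandwich covariance. Under independence the point estimates
coincide with the stacked-data GLM — a contract the test suite checks
against `glm()`, `lm()` and `sandwich::vcovCL()`. Convergence is declared
when the maximum relative coefficient change falls below $10^{-8}$ (at most
100 iterations). The working-correlation choice is a config option because
the source analysis specifies GEE but not the structure; robust standard
errors make the point largely moot for the quantities used here.

Saturated designs on moderate samples can contain arm-by-cycle cells whose
outcome is constant; the cell log-odds is then infinite and the fit would
diverge. The suite fitter detects such cells (and quasi-separated
directions flagged by the fitter) and merges them into their neighbours by
dropping the corresponding dummy, with a warning. This is the same "merge
where nothing distinguishes" logic as interaction pruning, applied where
the data force it.

### Pruning

Where the fitted interactions show no evidence of an arm or time effect the
suite collapses them (Wald tests on the robust covariance at 5%, iterated
to a fixed point): the non-SH hospitalisation model loses its arm terms
(the published probabilities are treatment-invariant), the non-hospital
occurrence model keeps time but typically loses arm terms beyond the first
cycle, and the conditional non-hospital cost and utility models may lose
both arm and time terms, collapsing to state-only means. The conditional
*hospital* cost models always retain all arm-by-time interactions, and the
two state-probability models stay saturated — maximum flexibility where
records cover the whole horizon. 5% was fixed as the decision rule once;
the published tables flag both 5% and 10%.

### Missing data

Two mechanisms, handled differently on purpose:

* **Questionnaire dropout** (utilities, self-reported non-hospital costs):
  assumed monotone; imputed by predictive mean matching. Each target is
  regressed on the already-complete predictors over observed cases, the
  coefficients are perturbed with a draw from their asymptotic normal
  distribution ("proper" imputation), and each missing case borrows the
  observed value of one of the $k = 5$ nearest-predicted-mean donors
  (uniform draw; $k$ is standard PMM practice, the source states only the
  method). Because imputations are observed donor values they respect the
  natural bounds — utilities below 1, costs at or above £0 — without
  clipping. Binary indicators are imputed through a linear probability
  score whose donors are observed 0/1s. Event-conditional costs are imputed
  only where the (possibly imputed) indicator is 1, preserving the
  convention that a positive cost implies the event. The default is
  M = 100 imputations; model coefficients are pooled by Rubin's rules
  (with the pruning decision taken once, on the pooled saturated fits, then
  applied uniformly so every imputed dataset shares one design).
* **Administrative censoring of hospital records**: follow-up lengths
  differ, so post-censoring cycles are simply absent and the unbalanced
  GEE panels accommodate them. Censoring is not imputed beyond the trial
  window — only the few censored hospital fields *inside* it are.

If a dataset's missingness is not exactly monotone the imputer warns and
proceeds in the declared ordering; predictors are restricted to
already-completed variables, so non-monotone patterns still impute in one
pass.

### Economic summaries and uncertainty

`icer()` labels FT *dominated* (costlier, less effective) or *dominant*
(cheaper, more effective) and otherwise reports $\Delta C / \Delta Q$;
incremental net health benefit is $\Delta Q - \Delta C/\lambda$ and net
monetary benefit $\lambda \Delta Q - \Delta C$ (identically
$\lambda \times$ INHB, an invariant under test). The probabilistic
sensitivity analysis draws every model's coefficient vector from a
multivariate normal on the link scale — mean at the (pooled) estimates,
covariance the robust (total, within + between imputation) covariance —
re-runs the engine per draw (default 10,000), and summarises the
$(\Delta C, \Delta Q)$ cloud as a cost-effectiveness plane and an
acceptability curve over £0–£50,000 per QALY in £500 steps. Drawn gaussian
utilities are truncated at 1. Each draw has its own seed sub-stream, so
enlarging a PSA never changes its earlier draws. A non-positive-definite
covariance (possible after pooling) is repaired to the nearest PSD matrix
by eigenvalue clipping, with a warning.

An alternative valuation replaces the empirical utilities and costs with
the NICE evidence-review parameters: state utilities 0.93 (non-RSH,
Beta(2025.242, 152.438)) and 0.68 (RSH, Beta(1529.743, 719.879)) and a
per-cycle RSH excess cost of ~£2,134 (Gamma, shape 4, scale 533.38); in
NICE-mode PSA those are drawn from their Beta/Gamma distributions.

### Numerical choices

* Discounting uses the cycle *start* time in years, $(1+r)^{-c/2}$, with
  midpoint/end exposed in config; the choice moves totals by under 2%. No
  half-cycle correction — the source describes none.
* Intervention costs (micro-costed in the source but never printed) are
  config inputs split equally over cycles 0–1 (first 12 months). The
  shipped placeholders (FT £1,745, TAU £250) were fixed once by closed-form
  arithmetic on the published tables so that the synthetic fixture's
  18-month incremental cost lands at the published ≈ +£1,705 scale — the
  hospital-side arithmetic contributes about +£210, leaving ≈ £1,495 to the
  intervention difference.
* ICER with $\Delta Q = 0$ exactly is reported as a label (signed infinity
  with a cost difference), never as a ratio.

## The synthetic cohort generator

The patient-level trial data sit under an NHS Digital sharing agreement and
cannot ship, so the generator emulates the structure the analysis needs,
with defaults transcribed from the published summary tables:

* ~398 patients per arm, 1:1 randomisation, ten 6-month cycles;
* per-cycle self-harm hospitalisation probabilities declining from 43–47%
  to 5–8% by arm; non-SH hospitalisation conditional on SH status (34% →
  9% / 27% → 6%); gamma conditional costs with the published arm-by-cycle
  means (shape 1.5 — right-skewed, dispersion of the same order as the
  means, chosen once as typical for hospital episode costs);
* non-hospital cost occurrence by arm and SH status for the three trial
  cycles, gamma magnitudes with state means £933.35 / £705.03 (shape 2);
* utilities drawn from a truncated normal on the EQ-5D-3L tariff range
  [−0.594, 1] around state means 0.674 (SH) / 0.792 (no SH), SD 0.22
  (consistent with the published standard errors of the utility
  differences). The truncation point sits within one SD of the non-SH
  mean, so the location parameter is moment-matched numerically — the
  *realised* state means equal the nominal ones, which is what the
  parameter-recovery tests require;
* deaths: hazard concentrated in cycles 6–7 of the FT arm (two deaths
  between years 3 and 4; none in TAU), absorbing, at cycle granularity;
* monotone questionnaire dropout (hazards 0.40/0.08/0.06 per trial cycle,
  matching the ~50% missingness of the published within-trial tables —
  which are themselves not perfectly monotone; a monotone hazard is the
  closest structure the imputation model assumes), and a hospital-record
  censoring distribution built from the published per-cycle missing-data
  counts (≈ 40% of patients still observed at months 54–60).

Covariates (gender 0.85 female, age 15–17 0.60, index cause self-poisoning
0.75, hospital-referred 0.55) are sampled independently — no joint
distribution is published — and enter the generating logistic model with
zero offsets by default, since the published rates are population-level.
The marginal proportions are realistic for UK adolescent self-harm cohorts
(self-poisoning dominant, large female majority).

What the generator does *not* emulate: episode-level HES/A&E records and
ICD coding (events enter at the cycle-indicator level the model consumes),
within-patient event dependence across cycles (the engine itself assumes
none — an acknowledged limitation), informative dropout or censoring
(missingness is MCAR given arm), and any true treatment effect on
utilities beyond what the state difference implies. Passing tests
therefore demonstrate that the machinery recovers known structure of this
kind, not that the real data satisfy these assumptions.

## Problem sizes used by the tests

Unit tests run on cohorts of 40–400 patients with 3–10 cycles; the
parameter-recovery suite uses 100 replicates of a complete 796-patient,
10-cycle cohort and requires agreement within three Monte-Carlo standard
errors; the end-to-end fixture run uses 398 patients per arm, 5
imputations, and a 1,000-draw PSA. These sizes were chosen to keep each
suite's Monte-Carlo error far below the tolerances it asserts. The
pipeline defaults remain the analysis-scale settings (M = 100, 10,000 PSA
draws).

## Known limitations

* No memory across cycles: the probability of a self-harm hospitalisation
  at cycle $c$ does not condition on earlier events, though repetition is
  surely autocorrelated in reality.
* No therapist-level clustering (many therapists over a 36-month
  recruitment window make it impractical; the source makes the same call).
* The "average participant" prediction evaluates covariate means on the
  linear-predictor scale — an approximation to population-averaged
  predictions; the published tables do not state their standardisation.
* The Kaplan–Meier death curve enters the PSA as fixed: with two events
  there is nothing useful to draw from, but it means mortality uncertainty
  is not propagated.
* A five-year horizon with no extrapolation beyond the records: the model
  deliberately says nothing about lifetime effects.
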