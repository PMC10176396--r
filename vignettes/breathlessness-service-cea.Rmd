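---
title: "From stated preferences to cost-effectiveness: the breathcea model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stated preferences to cost-effectiveness: the breathcea model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathcea)
```

## The problem

Breathlessness-triggered services (BSs) are short, multiprofessional
interventions for people with chronic breathlessness in advanced disease
(COPD, interstitial lung disease, lung cancer). Whether such a service is
worth commissioning depends on two linked questions: *which configuration
of the service will patients and carers actually take up*, and *is offering
it cost-effective once realistic uptake is taken into account*. breathcea
implements that two-stage analysis: a discrete choice experiment (DCE)
analysed with a conditional logit model, feeding a Markov cohort
cost-effectiveness model.

## Stage 1: the preference model

Each choice task shows two hypothetical service configurations plus a
"neither" (opt-out) alternative. A configuration is one level per
attribute: place of consultation (GP surgery, home visit, outpatient
clinic), nature of treatment review (non-medicinal only, comprehensive),
additional support (none, social worker alone, therapists plus social
worker) and waiting time to the first appointment (2, 4, 8 weeks). Two
further attributes — the expected change in breathlessness and in
healthcare use — are held fixed across all configurations, so they are
absorbed into the constant rather than varied.

The utility of alternative $j$ in task $t$ is linear in its attribute
coding:

$$U_{jt} = \beta_0\,\mathrm{any}_{j} + x_{jt}'\beta + \varepsilon_{jt},
  \qquad \varepsilon_{jt} \sim \text{Gumbel i.i.d.}$$

where $\mathrm{any}_j$ is 1 for a service and 0 for the opt-out (whose
systematic utility is normalised to zero), and $x_{jt}$ dummy-codes each
attribute against its reference level. The choice probability is the
softmax $P(j) = e^{V_j} / \sum_k e^{V_k}$, giving the conditional logit
likelihood, which `fit_conditional_logit()` maximises by Newton–Raphson
with the analytic score and information. The log-likelihood is concave, so
the optimum is global; the default start is the zero vector, convergence is
declared when the score's infinity norm drops below `1e-6`, and at most 200
iterations are taken (far more than the handful a concave problem needs —
step-halving guards the rare overshoot).

Because each respondent answers six tasks, the default reported covariance
is a cluster-robust sandwich grouped by respondent; the model-based inverse
information is kept alongside. Respondent-specific taste variation (mixed
logit) is deliberately out of scope: the estimator reports one coefficient
vector per (sub)group, and subgroups are compared with a likelihood-ratio
test (`lr_test()`) whose full model fits each group separately. Tasks
with no recorded choice are dropped task-wise, never respondent-wise; a
task with two chosen alternatives is rejected at load.

### Coefficients for all levels versus contrasts

Published preference figures for services of this kind often report a
weight for *every* level of an attribute (an effects-style presentation),
while a dummy-coded fit identifies only level-minus-reference contrasts.
`coefficient_set()` accommodates both: it stores per-level utility
contributions keyed `attribute:level`, and any level without an entry
contributes zero. A fitted set therefore carries only non-reference
contrasts, while a transcribed published set may carry all levels; both
price configurations through the same `configuration_utility()`. A
consequence worth noting: re-expressing an attribute against a different
reference level changes individual coefficients but leaves every
configuration's utility difference — and hence every uptake probability —
unchanged (the constant absorbs the shift), which the test suite verifies.

## Stage 2: uptake

Acceptance of a concrete configuration is modelled as a binary choice
between that configuration and the opt-out:

$$p(\text{uptake}) = \frac{e^{U}}{1 + e^{U}},$$

not as a share within a three-way task — the uptake number feeds a
take-it-or-leave-it decision node in the cohort model. Intervals come from
the delta method on the utility scale mapped through the inverse logit
(which keeps them inside $(0,1)$), or from a cluster bootstrap over
respondents when the raw choice data are available. On simulated data at
300 respondents the two intervals agree within 10% relative half-width.

## Stage 3: the Markov cohort model

Five mutually exclusive states: `usual_care`, `bs_effect` (first 12-week
cycle of benefit), `bs_extended_effect` (second cycle of benefit under the
extended-effects scenario), `no_change` (service taken, effect worn off —
usual-care payoffs, kept distinct so the trace records service history) and
absorbing `dead`. Three strategies: usual care; the service whose effect
disappears after one cycle; and the service with effects lasting two
cycles. The cycle length is 12 weeks (0.25 years) and the horizon 20
cycles (5 years), discounted at 3.5% per year compounded per cycle:
$(1.035)^{-0.25 t}$.

Design choices that were genuinely open:

* **Uptake** enters once, at model entry: the uptake fraction starts in
  `bs_effect`, the remainder follows usual care within the same strategy.
  There is no per-cycle re-offer and no decliner penalty.
* **Mortality switching.** The first cycle uses age- and sex-specific
  all-cause mortality; later cycles use respiratory mortality — the
  simplest reading of an "initial stage" rule; the boundary is the
  `all_cause_cycles` argument. Annual probabilities convert to per-cycle
  ones by $1-(1-p)^{0.25}$ (constant hazard within the year), and age
  advances every four cycles.
* **No half-cycle correction**: payoffs accrue on start-of-cycle
  occupancy. A correction would shave half a cycle's discounting off both
  arms and barely move the increments; a flag is deliberately not offered
  so that the two arms can never be corrected inconsistently.
* **Payoff parameters are grouped by trial arm**, not by state:
  `usual_care` and `no_change` share the control-arm cost and utility
  estimates, the two effect states share the intervention-arm estimates.
  Delta-method variance is therefore propagated per *estimated parameter*,
  avoiding the double-counting that treating the four live states as
  independent estimates would introduce — and the probabilistic
  sensitivity analysis samples the same four parameters, so the two routes
  agree (within Monte Carlo error) by construction rather than by luck.

Occupancy conservation is asserted at every cycle to $10^{-9}$ (the trace
is aborted on drift); tests verify conservation to $10^{-12}$ and that
`dead` is non-decreasing. Incremental results follow
$\mathrm{ICER} = \Delta C / \Delta Q$ with explicit dominance labels; a
zero $\Delta Q$ with non-zero $\Delta C$ is flagged `undefined` rather than
printed as $\pm\infty$.

## Uncertainty

Costs and QALYs are linear in the payoff means with weights accumulated
along the trace, so first-order (delta-method) intervals are exact given
normal inputs. The probabilistic sensitivity analysis re-samples the four
payoff parameters — gamma for costs, beta for utilities (method of
moments), optionally beta for uptake — and reruns both arms per draw; 1000
draws is the default, matching standard practice for this model size. The
acceptability curve reports, for each willingness-to-pay $\lambda$ on a
£0–£50,000 grid (£1,000 steps), the fraction of draws with strictly
positive net monetary benefit $\lambda\,\Delta Q - \Delta C$; ties count as
non-acceptance.

## What the generators emulate — and what they do not

The synthetic-data module defines the study conditions under which the
pipeline is exercised:

* `simulate_choice_data()` draws 256 respondents × 6 tasks (two random
  distinct services plus opt-out) and picks choices by Gumbel-error
  maximisation — exactly the data-generating process the conditional logit
  assumes. The default truth (`synthetic_truth()`) uses the published point
  estimates for this service type (any-service constant 1.52; GP surgery
  −0.30; outpatient clinic 0.16; home visit 0.15; comprehensive review
  0.15; holistic support 0.19; no support −0.23; social worker alone
  −0.15) plus synthetic waiting-time placeholders (+0.25 for 2 weeks,
  +0.10 for 4 weeks against the 8-week reference), chosen once so that
  shorter waits are preferred with magnitudes comparable to the place
  coefficients. Tasks are randomly paired with a balance check rather than
  drawn from a blocked fractional-factorial catalogue; an explicit design
  can be loaded from file instead.
* `synth_trial_payoffs()` emulates a 100-per-arm trial: per-patient cycle
  costs gamma with mean £2,000 and CV 0.5 under usual care, EQ-5D normal
  with mean 0.70 and SD 0.15 truncated to $[-0.6, 1]$; the effect period
  changes costs by −£780/cycle and utility by +0.06. With the
  base-case uptake of 0.85 these magnitudes land the deterministic
  increments near −£660 and +0.013 QALYs in the first cycle — the right
  order of magnitude for a brief intervention — but they are configured
  values, not the unpublished trial estimates.
* `synth_life_table()` is Gompertz-type: 8%/year all-cause mortality at 75
  for men growing 10%/year of age, women at 0.8×, respiratory mortality
  35% of all-cause. These are plausible for an elderly COPD cohort but
  synthetic; the model accepts any life-table CSV.

Passing tests therefore demonstrate *internal correctness and statistical
calibration* — the estimator recovers known truths with nominal coverage,
the trace conserves probability, uncertainty propagates consistently — not
agreement with the original study's numbers, which depend on unpublished
trial payoffs and a coefficient vector only partly in print. Real choice
data also bring features the generator omits: respondent-specific taste
variation, attribute non-attendance, serial non-responses.

## Problem sizes

The test suite fits 200 replicates at 300 respondents × 6 tasks for
parameter recovery, 1000 null simulations (100 respondents each) for
likelihood-ratio calibration, and 1000-draw sensitivity analyses — sizes at
which the binomial and Monte Carlo error bands quoted in the tests are
meaningful while a full run stays around a minute. The analysis scripts use
the study geometry (256 × 6) throughout.

## Known limitations

* Plain conditional logit only: no mixed, nested or latent-class models,
  and no willingness-to-pay monetisation of waiting time (though linear
  waiting coding supports willingness-to-wait arithmetic).
* The Markov structure is the five named states; no microsimulation, no
  informal-care or productivity costs, no expected-value-of-information
  analysis.
* The experimental design generator does not optimise D-efficiency.
* Uptake uncertainty enters the PSA only if given a distribution; the
  deterministic base case treats it as fixed.
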