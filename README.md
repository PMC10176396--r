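# breathcea

Economic evaluation of breathlessness-triggered services (BSs) — short,
holistic, multiprofessional interventions for older people whose
breathlessness remains severe despite optimal treatment of the underlying
disease (COPD, interstitial lung disease, lung cancer). The package is for
health economists and health-services researchers who want to couple
*stated preferences* for service attributes with *cost-effectiveness
modelling*: which configuration of a service would patients and carers
actually take up, and is offering it good value once that uptake is taken
into account?

## The model

**Preferences.** Discrete-choice-experiment data (each task: two
hypothetical service configurations plus a "neither" opt-out) are analysed
with a conditional logit model. Alternative *j*'s utility is

U_j = β₀·any_j + x_j′β + ε_j,  ε_j ~ Gumbel i.i.d.,

where `any_j` indicates a service over the opt-out (normalised to utility
0) and x_j dummy-codes place of consultation, nature of treatment review,
additional support and waiting time against reference levels. Choice
probabilities are softmax in the utilities; `fit_conditional_logit()`
maximises the likelihood by Newton–Raphson with analytic score and
information, reporting cluster-robust (by respondent) standard errors,
with likelihood-ratio subgroup tests and a respondent-level bootstrap.

**Uptake.** A configuration's acceptance probability against the opt-out
is p = eᵁ/(1+eᵁ), with delta-method or bootstrap intervals
(`uptake_probability()`, `rank_configurations()`).

**Cost-effectiveness.** Uptake feeds a five-state Markov cohort model
(usual care, service effect, extended effect, no change, dead) over twenty
12-week cycles (5 years) with 3.5 %/year discounting, all-cause mortality
in the first cycle and respiratory mortality thereafter. Outputs are
discounted costs and QALYs, ΔC, ΔQ, ICER = ΔC/ΔQ with dominance flags and
delta-method CIs (`run_cohort()`, `incremental_results()`), Monte Carlo
probabilistic sensitivity analysis and cost-effectiveness acceptability
curves (`draw_psa()`, `ceac()`).

Seedable generators (`simulate_choice_data()`, `synth_trial_payoffs()`,
`synth_life_table()`) produce every input, so the whole pipeline runs and
is tested without access to trial data. See the methods vignette
(`vignettes/breathlessness-service-cea.Rmd`) for assumptions, parameter
defaults and limitations.

## Worked example

```r
library(breathcea)

design <- default_attributes()
dce <- simulate_choice_data(design, synthetic_truth(design),
                            n_respondents = 256, n_tasks = 6, seed = 2024)
fit <- fit_conditional_logit(dce)
print(fit)
#> conditional logit fit: 1536 tasks, 256 respondents; converged in 6 iterations
#>                                      estimate     se  ci_low ci_high
#> asc                                    0.7698 0.1289  0.5171  1.0225
#> place:home_visit                       0.4279 0.0955  0.2407  0.6151
#> place:outpatient_clinic                0.3929 0.0886  0.2191  0.5666
#> review:comprehensive                   0.1627 0.0779  0.0101  0.3153
#> support:social_worker_only             0.1207 0.0832 -0.0423  0.2837
#> support:therapists_and_social_worker   0.5367 0.0893  0.3617  0.7116
#> waiting:2_weeks                        0.4246 0.0838  0.2603  0.5888
#> waiting:4_weeks                        0.2602 0.0848  0.0941  0.4264
#> log-likelihood: -1396.048 over 1536 tasks
```

Positive coefficients are preferences relative to the reference levels (GP
surgery, non-medicinal review, no support, 8-week wait); the constant
(`asc`) is the value of being offered *any* service over "neither".

```r
most <- service_config(place = "outpatient_clinic", review = "comprehensive",
                       support = "therapists_and_social_worker",
                       waiting = "2_weeks")
uptake_probability(fit$coefficients, most)
#> uptake 90.8% (U = 2.287), 95% CI 88.5% to 92.6% [delta]

cohort <- cohort_spec(uptake = 0.908)   # 75-year-old man with COPD
lt  <- synth_life_table()
pay <- synth_trial_payoffs(seed = 2025)$payoffs
uc <- run_cohort(cohort, strategy_spec("usual_care"), lt, pay)
bs <- run_cohort(cohort, strategy_spec("bs"), lt, pay)
incremental_results(uc, bs)
#> usual_care vs bs
#>   Costs (£)                -687 (-888 to -485)
#>   Health outcomes (QALY)   0.011 (0.003 to 0.019)
#>   ICER (£/QALY)          -60652  [dominant]

curve <- ceac(draw_psa(cohort, lt, pay, n = 1000, seed = 2026))
range(curve$acceptability)
#> [1] 1 1
```

Offering the service costs less and yields more QALYs than usual care
(`dominant`); the acceptability curve equals 1 across the whole
£0–£50,000/QALY willingness-to-pay grid — at any threshold, every Monte
Carlo draw favours the service.

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline and write
tables to `results/`:

1. `01_simulate_inputs.R` — choice data (256 × 6 with opt-out), trial-like
   payoffs, life table, plus sidecar truth files.
2. `02_fit_preferences.R` — conditional logit fit, coefficient JSON,
   subgroup likelihood-ratio test.
3. `03_uptake_ladder.R` — uptake for the seven-step configuration ladder
   from least to most preferred service.
4. `04_markov_ce.R` — cost-effectiveness for 75-year-old men and women,
   service with and without extended effects, with per-cycle traces.
5. `05_psa_ceac.R` — 1000-draw sensitivity analysis and acceptability
   curves.

Run them in order from the repository root: `Rscript analysis/01_simulate_inputs.R`, …

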