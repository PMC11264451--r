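# cureselect

Penalized semi-parametric mixture cure models for competing-risks cohorts.

`cureselect` is for survival analyses in which a fraction of subjects will
never experience the event of interest — the motivating case is childhood
leukemia followed for relapse, with death before relapse as a competing
event and a clearly plateauing relapse Kaplan–Meier curve. It fits, per
cause (other causes recoded as censoring), the mixture cure model

```
S_pop(t | x) = 1 − π(x) + π(x) · S_u(t | x)
π(x)   = expit(θ₀ + x'θ)            (incidence: who is susceptible)
S_u(t|x) = S₀(t)^exp(x'β)            (latency: Cox PH, Breslow baseline)
```

by EM with the zero-tail constraint, and performs variable selection by
adding LASSO or SCAD (shape a = 3.7) penalties on both components inside
the EM, with the tuning parameter λ chosen by AIC or BIC over a
warm-started path. Incidence effects are reported as odds ratios
`exp(θ)`, latency effects as hazard ratios `exp(β)`; confidence intervals
come from a subject-level percentile bootstrap. Nonparametric companions —
Kaplan–Meier, Aalen–Johansen cumulative incidence, and the Maller–Zhou
sufficient-follow-up check — justify and contextualize the cure model.
Because registry data of this kind are typically not shareable, the
package includes a synthetic-cohort generator with known ground truth
(`leukemia_scenario()`, `sparse_scenario()`) used by its entire validation
suite.

## Worked example

```r
library(cureselect)

cohort <- simulate_cohort(leukemia_scenario(), seed = 7)   # 187 subjects
table(cohort$cause)                 # 0 censored / 1 relapse / 2 death
#>   0   1   2
#> 123  22  42

km_plateau(kaplan_meier(cohort, "relapse"))
#> [1] 0.8579747
maller_zhou_test(cohort, "relapse")
#> Maller-Zhou sufficient follow-up check
#>   n = 187, events in (2t* - t_max, t*] = 1, q_n = 0.0053
#>   alpha_n = (1 - q_n)^n = 0.3669  (level 0.05)
#>   verdict: no evidence of sufficient follow-up
#>   KM plateau: 0.858 - consistent with a nonzero cured fraction

report <- run_cause_specific_analysis(cohort, "relapse", criterion = "bic")
report$comparison
#> # A tibble: 3 × 5
#>   method        df loglik   aic   bic
#> 1 SCAD           1  -135.  271.  275.
#> 2 LASSO          1  -135.  271.  275.
#> 3 Full model    29  -119.  296.  389.
```

The relapse curve plateaus at 0.86 with the last observation censored —
consistent with a cured fraction — while the deliberately conservative
Maller–Zhou p-value stays equivocal on this draw because one late relapse
stretches the largest event time toward the end of follow-up; at 187
subjects that single count dominates the statistic. In the comparison
table the BIC of the SCAD-penalized model is far below the full
29-parameter model: at ~22 relapses, the full model is overparameterized
(its coefficient table shows the inflated, unstable estimates typical of
sparse registry cells) while BIC strips this draw down to the
intercept-only model. `tidy(report)` gives one row per coefficient with
its odds/hazard ratio; `predict(fit, newdata, type = "cure")` gives
per-patient cure probabilities.

A shell front end mirrors the R interface
(`inst/cli/cureselect simulate|describe|fit|report`); see `?cli_main`.

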