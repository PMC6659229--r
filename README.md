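# responderMI

Simulation pipeline for comparing missing-data strategies in **responder
analysis** of a dichotomized continuous outcome from a two-arm
longitudinal randomized trial.

## The problem

Trials with a continuous longitudinal outcome (for example a
patient-reported symptom scale measured at baseline and three follow-up
visits) are often reported as a responder analysis: subject *i* is a
responder when the change from baseline reaches a threshold,

```
R_i = I(Y_i4 − Y_i1 ≥ λ),
```

and the arms are compared on the difference in responder proportions
θ = p_A − p_B with a two-proportion test. When subjects drop out, R_i is
undetermined, and the analyst must choose a missing-data strategy:

* **NRI** — non-response imputation: count every undetermined subject as
  a non-responder (single imputation, recommended in regulatory settings
  but known to be biased);
* **IBD** — impute before dichotomizing: multiply impute the continuous
  outcomes by fully conditional specification (FCS / chained equations),
  then dichotomize each completed dataset;
* **DTI** — dichotomize then impute: impute the partially observed binary
  R directly through a logistic conditional in the FCS sequence.

MI estimates are pooled with Rubin's rules
(T = W + (1 + 1/M)·B, df = (M−1)(1 + W/((1+1/M)B))²). The package
generates complete trials from a random-intercept model
`Y_ij = μ_arm,j + b_i + ε_ij` (σ_b = 12, σ_ε = 7), imposes monotone
missing-at-random dropout under six calibrated propensity mechanisms
(lack of efficacy, arm-dependent direction, differential rates, logistic
forms, adverse-event-driven), and measures percent bias, coverage, power
and type I error of each strategy over replicated scenarios. See the
methods vignette (`vignettes/responder-imputation.Rmd`) for the models
and all design choices.

## Worked example

One simulated trial under the linear profile (arm A improves by 6 points,
arm B flat; true responder rates 25.9% vs 10.5% at λ = 12.4), with
lack-of-efficacy dropout calibrated to 30% endpoint missingness:

```r
library(responderMI)

trial <- simulate_trial(response_profile("linear"), n = 200, seed = 11)
trial <- generate_cv(trial)

spec   <- dropout_spec(model_id = 1, target_rate = 0.30)
cutoff <- calibrate_cutoff(
  function(r) simulate_trial(response_profile("linear"), 200, seed = 100 + r),
  spec, seed = 12)
mask     <- apply_dropout(trial, spec, cutoff, seed = 13)
observed <- apply_mask(trial, mask)
mask
#> Monotone dropout mask: model 1, 200 subjects, 41.0% missing at visit 4 (cutoff 4.3750)

full <- diff_proportions(classify_responders(trial), trial$arm)
sprintf("full data: p_A = %.3f, p_B = %.3f, diff = %.3f",
        full$p_A, full$p_B, full$diff)
#> "full data: p_A = 0.270, p_B = 0.080, diff = 0.190"

pool_result(run_strategy(observed, imputation_spec("NRI")))
#> Pooled difference in proportions: 0.0900 (95% CI 0.0097, 0.1703), p = 0.02806
#>   M = 1, within = 0.00168, between = 0, df = Inf
pool_result(run_strategy(observed, imputation_spec("IBD", M = 30), seed = 14))
#> Pooled difference in proportions: 0.1487 (95% CI 0.0247, 0.2726), p = 0.01895
#>   M = 30, within = 0.00263, between = 0.00129, df = 257.3
pool_result(run_strategy(observed, imputation_spec("DTI", M = 30), seed = 14))
#> Pooled difference in proportions: 0.1690 (95% CI 0.0260, 0.3120), p = 0.02086
#>   M = 30, within = 0.00283, between = 0.00232, df = 137.9
```

On this dataset (whose realized missingness, 41%, is one draw around the
30% scenario target) the full-data difference is 19.0 points. NRI halves
it to 9.0 — dropout here removes low scorers, who in arm B include most
of the would-be responders — while both MI strategies stay near the
full-data answer and correctly widen the interval for the imputation
uncertainty (between-imputation variance > 0, finite Rubin df).

Replicated scenario metrics, in the shape of the published comparison
tables:

```r
metrics <- run_scenario(
  scenario_config("linear", dropout_spec(1, 0.30), n_sim = 200),
  seed = 1)$metrics
run_study(profiles = "linear", model_ids = 1:6, rates = 0.30,
          n_sim = 200, seed = 1, out_dir = "results")  # CSVs + JSON
```

A command-line entry point is installed as `exec/respondermi` with
subcommands `simulate`, `impute`, `run-study`, `metrics`.

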