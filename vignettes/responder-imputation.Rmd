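---
title: "Missing-data strategies for responder analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-data strategies for responder analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(responderMI)
```

## The problem

Many trials report a *responder analysis*: a continuous outcome $Y_{ij}$
(subject $i$, visit $j = 1, \dots, 4$) is dichotomized at the endpoint into
$R_i = I(C_i \ge \lambda)$, where $C_i = Y_{i4} - Y_{i1}$ is the change from
baseline, and the arms are compared on the difference in responder
proportions $\theta = p_A - p_B$. When subjects drop out, $R_i$ is
undetermined. Three ways of handling that are implemented here:

* **NRI** (non-response imputation): every undetermined subject is counted
  as a non-responder. A single completed dataset; no imputation
  uncertainty is propagated.
* **IBD** (impute before dichotomizing): the continuous outcomes are
  multiply imputed by fully conditional specification (FCS), then each
  completed dataset is dichotomized.
* **DTI** (dichotomize then impute): $R_i$ is computed where determined
  and the partially observed binary indicator is imputed directly through
  a logistic conditional inside the same FCS sequence.

MI estimates are combined with Rubin's rules; the package's simulation
layer measures percent bias, coverage, power and type I error of each
strategy over replicated trials.

## Data-generating model

`simulate_trial()` draws a two-arm trial with equal allocation
($N/2$ per arm, arm A first; downstream code never assumes ordering):

$$Y_{ij} = \mu_{a(i),j} + b_i + \epsilon_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad \epsilon_{ij} \sim N(0, \sigma_\epsilon^2),$$

a random-intercept (compound-symmetry) model with within-person
correlation $\sigma_b^2 / (\sigma_b^2 + \sigma_\epsilon^2)$. Defaults
$\sigma_b = 12$, $\sigma_\epsilon = 7$ give correlation $0.75$, typical of
patient-reported outcome scales scored 0–100. Four mean-trajectory
profiles are built in (`response_profile()`): a linear profile where only
arm A improves (A $(65,67,69,71)$ vs B flat at 65), a crossing non-linear
profile with the same endpoint difference, and two null profiles with no
endpoint difference, used for type I error.

Because $b_i$ cancels in the change score, $C_i \sim
N(\Delta_a, 2\sigma_\epsilon^2)$ with $\Delta_a$ the mean change in arm
$a$, so the true responder rate has the closed form
$1 - \Phi((\lambda - \Delta_a)/\sqrt{2\sigma_\epsilon^2})$
(`true_response_rate()`). At the default threshold $\lambda = 12.4$ the
linear profile gives rates of about 25.9% (arm A) and 10.5% (arm B) and
roughly 80% power at $N = 200$; empirical studies of this design quote
25.6/10.6, and the simulation layer accepts such empirical values as an
override for the bias reference (`scenario_config(pi_A=, pi_B=)`).

Two auxiliaries emulate covariates an imputer might use:

* `generate_cv()` appends a normal covariate with target correlation
  $\rho = 0.3$ to $Y_4$ (mean 38.0, SD 62.7), built conditionally:
  $CV = \mu + \sigma(\rho\, z(Y_4) + \sqrt{1-\rho^2}\, e)$ where $z(Y_4)$
  standardizes $Y_4$ by its *arm-specific* population moments. The
  within-arm population correlation is exactly $\rho$ by construction;
  marginally it is attenuated by the factor
  $\sqrt{193/202} \approx 0.98$ under the linear profile because the arm
  means differ at the endpoint.
* `generate_ae()` draws a two-state adverse-event process: none at
  baseline, arm-specific initial probabilities (0.3 arm A, 0.5 arm B) at
  visit 2, then first-order conditionals per arm for visits 3–4
  (`default_ae_table()`).

## Dropout mechanisms

Six missing-at-random dropout propensities are implemented
(`dropout_spec()`, `propensity()`), all acting on the *previous* visit's
outcome — and for model 6 the current visit's AE status — so missingness
depends on observed data only:

1. lack of efficacy: $1 - \Phi(Y_{j-1})$, with $\Phi$'s mean/SD estimated
   from the at-risk subjects' $Y_{j-1}$, pooled over arms, per dataset;
2. arm-dependent direction: arm A drops when low, arm B when high;
3. the reverse of 2;
4. differential rates: model 1 scaled by $w_A = 0.3$ in arm A,
   $w_B = 1$ in arm B;
5. logistic lack of efficacy $1/(1 + e^{b_1 Y_{j-1}})$, $b_1 = 0.01$;
6. efficacy and tolerability $1/(1 + e^{b_1 Y_{j-1} + b_2 AE_j})$,
   $b_2 = -0.40$ (an AE raises the dropout propensity). When a subject
   drops, AE values strictly after the dropout visit are masked too; the
   AE at the dropout visit stays observed because the mechanism
   conditions on it, which is what keeps the process MAR.

**Realization and calibration.** A subject at risk at visit $j$ drops when
their propensity exceeds `cutoff` times an independent uniform, so the
realized per-visit probability is $\min(1, p_{ij}/\text{cutoff})$ —
*exactly proportional* to the stated propensity. (The alternative reading,
thresholding $p_{ij} U_{ij}$ itself, realizes the concave transform
$1 - \text{cutoff}/p$, which truncates low propensities entirely and
breaks model 4's arm ratio; we verified it produces a far more extreme
differential pattern than the proportional form.) The cutoff is a single
scenario-level constant calibrated by bisection (`calibrate_cutoff()`) so
the mean endpoint missingness over 200 pilot datasets hits the target (30%
or 50%) within 0.005; pilot data and uniforms are drawn once and reused
across bisection iterates, making the search deterministic. Calibrating
per scenario rather than per dataset keeps each dataset's missingness
independent of its own realized outcomes beyond the propensities
themselves; per-dataset exact-count selection would tie every subject's
missingness to the whole sample. Dropout is monotone by construction:
visits are processed in order and everything after the first missing
visit is missing.

## The FCS engine

`fcs_impute()` follows the standard chained-equations recipe. Starting
values are filled sequentially in temporal order ($Y_2, Y_3, Y_4$, then
AE series, then $R$ for DTI), each variable regressed on the variables
complete at that point and replaced by its model prediction. Each of $M$
imputations then runs 10 full cycles; every cycle re-fits each
conditional on the current completed data and redraws that variable's
missing entries:

* **Continuous** conditionals use proper Bayesian linear-regression
  draws under flat priors: $\sigma^2$ from its scaled inverse-$\chi^2$
  posterior, coefficients from their conditional normal, then missing
  values as linear predictor plus $N(0, \sigma^2)$ noise. Rank-deficient
  designs get a $10^{-4}$ ridge jitter (logged).
* **Binary** conditionals fit logistic regression by IRLS and draw
  coefficients from the asymptotic normal approximation
  $N(\hat\beta, (X'WX)^{-1})$, then missing values as Bernoulli draws.

**Separation.** Under DTI the responder conditional is *always* completely
separated: $R$ is a deterministic function of $Y_1$ and $Y_4$, both of
which are predictors. A pure numerical jitter ($10^{-4}$ on the
information matrix) proved degenerate during development — the penalized
optimum has very large coefficients with vanishing IRLS weights, the
information matrix collapses to the jitter, and coefficient draws flip
entire imputations at once, inflating both arm proportions and the model
SE while destroying power. The fallback therefore uses a
weakly-informative ridge: prior SD 10 on the intercept and 2.5 per
standardized slope — the standard default for weakly-informative logistic
priors — floored at $10^{-4}$ for constant columns. With it the penalized
fit is bounded, its information retains the data's curvature, and draws
perturb the imputation threshold rather than destroying it. Single-class
conditionals impute the observed class; a non-converged penalized fit
falls back to intercept-only prevalence draws. All fallbacks are counted
in the result.

The number of cycles (10) matches the FCS burn-in default of the
software used for the original simulations; with monotone patterns and
sequential starts the chain is effectively stationary after the first
cycle, so this choice is conservative. DTI's responder conditional
includes $Y_4$ — the literal model statement — although conditioning a
deterministic child on its parent is statistically unusual;
`imputation_spec(dti_exclude_endpoint = TRUE)` provides the sensitivity
variant.

Two computational shortcuts change nothing statistically and preserve the
RNG stream exactly: the starting fill is deterministic and computed once
per run, and conditionals whose fitting rows contain no imputed values
under monotone dropout (the responder indicator and $Y_4$, both fit on
completers) are fit once and only redrawn per cycle.

## Analysis and pooling

`diff_proportions()` uses the unpooled Wald form
$\hat p_A - \hat p_B$ with
$SE = \sqrt{\hat p_A \hat q_A / n_A + \hat p_B \hat q_B / n_B}$ and a
two-sided z-test at $\alpha = 0.05$; the original analysis names only
"difference in proportions", and the Wald form is what Rubin's rules pool
naturally. Degenerate SEs (both arms at 0 or 1) are floored at machine
epsilon and flagged; they arise in tiny fixtures only. `rubin_pool()`
combines $M$ estimates with the classic components (within $W$, between
$B$, total $T = W + (1 + 1/M)B$) and degrees of freedom
$(M-1)(1 + W/((1+1/M)B))^2$, treating $B = 0$ as infinite df; at
$N = 200$ the Barnard–Rubin small-sample correction is negligible, so the
classic formula is used. NRI gets the plain Wald z interval.

## Scenario metrics

`run_scenario()` executes one cell: calibrate the cutoff, then per
replicate simulate, mask, run every strategy, pool. Seeds are
hierarchical (scenario seed → replicate substream → per-strategy
imputation substream), so any replicate is reproducible in isolation.
`summarize_scenario()` reports, on the percentage-point scale of the
published tables: mean arm proportions, mean difference with the average
95% CI, percent bias
$100((\bar p_A - \bar p_B) - (\pi_A - \pi_B))/(\pi_A - \pi_B)$, coverage,
the fraction of replicates with $p < 0.05$ (power or type I error),
$MCSE = SE_{emp}/\sqrt{n_{sim}}$, MSE, the mean model SE and the
empirical SE. The true rates $\pi$ default to the analytic oracle; the
published empirical values (25.6/10.6 for the linear profile) can be set
explicitly to reproduce table rows on their own scale. The identity
$MSE = SE_{emp}^2 (n_{sim}-1)/n_{sim} + \text{bias}^2$ is enforced by a
test. `simulation_size()` inverts the MCSE formula; with the planning
values (SD 6.0, MCSE cap 0.15) it returns the original study's 1600
replicates. Null profiles have a zero true difference, so percent bias is
refused there and the significance rate is reported as type I error.

## What the generator does and does not emulate

The synthetic world is normal at every stage: continuous outcomes with a
shared random intercept, normal auxiliary covariate, Bernoulli AE chains,
MAR monotone dropout. Green tests therefore establish correctness of the
machinery and reproduction of the published simulation's behavior *within
that world*. They do not establish robustness to non-normal or ordinal
outcomes (imputed values can fall outside a bounded scale — a known
limitation), to intermittent missingness, or to MNAR dropout, none of
which are simulated. The real-data entry point (`read_trial_csv()`)
accepts any wide-format trial table but inherits the same modeling
assumptions.

## Numerical choices

* IRLS convergence at max step $10^{-6}$, 25 iterations unpenalized / 50
  penalized; IRLS weights floored at $10^{-10}$; fits with
  $\max|\hat\beta| > 20$ are treated as separated.
* Cutoff bisection: tolerance 0.005 on the pilot mean, up to 60 iterates,
  upper bracket doubled from 1 until the target is straddled.
* `simulation_size()` snaps to the nearest integer before the ceiling to
  absorb floating-point overshoot of exact ratios.
* Responder classification is inclusive at the boundary
  ($C_i \ge \lambda$), and undetermined status is an explicit `NA`,
  never silently zero.
* Seed derivation uses Lehmer-style mixing kept below $2^{31}-1$.
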