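# micure

Mixture cure models for **mixed-case interval-censored** time-to-event data,
with a support-vector-machine incidence component.

## The problem

In follow-up studies with periodic examinations, the event time is only ever
known to lie between two visits: each subject carries an interval
`(u_left, u_right]`, with left censoring (`u_left = 0`) and right censoring
(`u_right = Inf`) as special cases, and the *number* of visits varies by
subject (mixed-case interval censoring). When part of the population is
*cured* — will never experience the event — the population survival curve
plateaus, and the cured status is unknown exactly for the right-censored
subjects. `micure` fits the two-component mixture cure model

    S_p(t | x, z) = 1 - pi(z) + pi(z) * S0(t)^exp(x'beta)

where `pi(z)` is the uncured (susceptible) probability given incidence
covariates `z`, and the latency of the uncured follows a proportional-hazards
structure over a nonparametric Turnbull baseline `S0`, estimated once from
all censoring intervals and then frozen.

The incidence is modelled either by

* an RBF-kernel **SVM** whose decision values are converted to probabilities
  by **Platt scaling** — capturing non-linear cured/uncured boundaries — or
* **logistic regression** (the classical comparator).

Estimation is an EM-type algorithm: E-step weights give each right-censored
subject its posterior uncured probability; the SVM M-step imputes the
missing cure labels `M = 5` times from those weights, refits SVM + Platt per
imputation and averages; the latency coefficients maximize the weighted
interval-censored likelihood by Nelder-Mead. Hyperparameters are tuned by
stratified 10-fold cross-validation, and standard errors come from a
nonparametric bootstrap. A data generator reproduces the four benchmark
simulation scenarios (and a synthetic decompression-sickness-like fixture),
with per-subject ground truth retained for evaluation (bias/MSE, ROC/AUC,
and a simulation-based ROC for data whose cure labels are unknown).

See the methods vignette (`vignettes/micure-methods.Rmd`) for the model,
algorithmic choices, and known limitations.

## Worked example

```r
library(micure)

sim <- generate_mcic(2, n = 300, seed = 42)   # non-linear incidence boundary
fit <- micure(sim$data, model = "svm", seed = 42,
              control = micure_control(max_iter = 15))
fit
#> Mixture cure model for mixed-case interval-censored data
#>   incidence: SVM (RBF kernel, Platt-scaled) | latency: PH over Turnbull baseline
#>   n = 300 (left 73 / interval 26 / right-censored 201)
#>   tuned hyperparameters: gamma = 0.0625, Q = 32
#>   latency coefficients:
#>   xz_z1   xz_z2
#> -2.8700  3.0167
#>   mean fitted uncured probability: 0.518
#>   EM: 15 iteration(s), NOT converged (criterion 1.37e-01)

fit <- bootstrap_se(fit, B = 25, seed = 43)
summary(fit)
#> Latency coefficients:
#>       Estimate Boot. SE z value Pr(>|z|)
#> xz_z1  -2.8700   0.5028  -5.708 1.14e-08 ***
#> xz_z2   3.0167   0.5409   5.577 2.45e-08 ***
#> Mean fitted cure rate: 0.482

roc_auc(predict(fit, type = "uncured"), sim$truth$J_true)$auc
#> [1] 0.695
```

What these numbers mean: the sample splits into 99 subjects known to be
uncured (left/interval-censored) and 201 right-censored subjects of unknown
status. The fitted latency coefficients say the event arrives faster for
subjects with small `z1` and large `z2` (true generating values are −5 and
5; estimates over the frozen marginal baseline are attenuated — see the
vignette). The mean fitted cure rate 0.482 tracks the scenario's true cured
share (≈0.45 at these settings), and the fitted uncured probabilities
discriminate true cured from uncured subjects with AUC 0.695 — far above
what a logistic incidence achieves on this interaction-driven boundary
(≈0.50, coin-flip). The SVM EM's stopping criterion sits at its
multiple-imputation noise floor, so the iteration cap is the effective
stopping rule; "NOT converged" reports that honestly.

Monte-Carlo studies and the real-data-style workflow are scripted:

```r
run_simulation_study(2, n = 300, reps = 50, models = c("svm", "logit"), seed = 1)
run_hdsd_workflow(generate_hdsd_like(238, seed = 1)$data, seed = 2)
```

A thin command-line interface (`inst/cli/micure`) exposes `simulate`, `fit`,
`bootstrap`, `evaluate` and `reproduce` subcommands over the same functions;
see `?run_cli`.

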