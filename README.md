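# lqrg

Radiobiological modelling of time-dependent tumor control after
fractionated radiotherapy.

## What this is for

Radiation oncologists and modellers comparing fractionation schemes need
models that track loco-regional progression-free survival (LPFS) over
years of follow-up, not just a dose-response at one time point. This
package implements two tumor control probability (TCP) pipelines for that
task and the machinery to fit and compare them on right-censored patient
data:

* an **extended linear-quadratic model** incorporating the four "R"s of
  radiobiology — repair, redistribution, reoxygenation, repopulation —
  plus delayed regrowth and Gompertzian post-treatment growth, mapped to
  control probability through Gaussian clonogen statistics;
* the **classical LQ baseline** with Poisson/binomial TCP.

The core survival model for a schedule of total dose *D* delivered in
overall time *T*, evaluated *t* after the end of treatment:

    ln SF(t) = −αD − βG(τ_R)D² + ½σ²G(τ_S)D²
               + ln2·max(0, T−T_k)/τ_P + (ln2·t/τ_P)^δ

    TCP(t) = 1 − Φ((K₀·SF(t) − K_cr)/σ_k),   K₀ = ρV

where G(τ) is the generalized Lea-Catcheside dose-protraction factor,
computed exactly for instantaneous fractions and by adaptive quadrature
for finite-duration delivery. TCP(t) is fitted to Kaplan-Meier LPFS
estimates by minimizing the mean absolute error with a multi-start
gradient descent; models are compared by Laplace-surrogate log-likelihood,
AIC and leave-one-out cross-validation. A synthetic-cohort generator
(inverse-transform sampling from the model-implied survivor curve, with
administrative censoring) stands in for the clinical cohort, which is not
public.

## Worked example

Build the representative schedule of a hypo-fractionated treatment group
(mean GTV dose 62.89 Gy, median fraction size 2.8 Gy), inspect its
radiobiology, and fit the model to a simulated 103-patient cohort:

```r
library(lqrg)

sched <- group_schedule(62.89, 2.8)
sched
#> Fractionation schedule: 22 fraction(s), D = 62.89 Gy, T = 696 h (4.14 weeks)
#>   target total dose: 62.89 Gy
#>   uniform 2.859 Gy per fraction

p <- lqrg_params()                      # packaged fitted NSCLC values
round(lea_catcheside_g(sched, p$tau_R), 4)   # repair-weighted protraction
#> [1] 0.0471
round(bed_lqrg(p, sched), 2)                 # biologically effective dose, Gy
#> [1] 90.42
round(tcp_time_curve(p, sched, tumor_spec(108.51, p$rho), c(12, 24, 36)), 3)
#> [1] 0.551 0.294 0.134
```

The 22-fraction schedule spans 4.1 weekday weeks; its complete-repair
protraction limit is 1/22 = 0.045, rising to 0.047 at the fitted repair
time of 6.32 h. The model predicts 29.4% loco-regional control at two
years for this group — and higher control for larger fraction sizes, the
qualitative clinical finding.

```r
rec  <- simulate_cohort(cohort_spec(), p, seed = 7)   # three groups, n = 103
data <- fit_data_from_cohort(rec, cohort_schedules(cohort_spec()), rho = p$rho)
fit  <- fit_tcp("lqrg", data,
                free = c("alpha", "beta", "sigma2", "delta", "rho"),
                control = fit_control(max_iter = 1000, n_starts = 2),
                seed = 7)
fit
#> TCP fit (LQRG): 5 free parameter(s), 103 samples
#>   MAE = 0.058462  logLik = 118.1  AIC = -226.1  converged: TRUE
#>   alpha    0.066492
#>   beta     0.10421
#>   sigma2   0.19338
#>   delta    0.26301
#>   rho      2299898382
```

The fit recovers the generating radiosensitivity (α = 0.0665 vs 0.06691)
from the censored cohort, with a mean absolute LPFS error of 5.8
percentage points. `model_comparison()` and `loo_accuracy()` add AIC and
cross-validated accuracy; `run_full_analysis()` runs the whole workflow
(simulate or load a cohort, estimate LPFS, fit both models, emit CSV/JSON
reports) from one YAML config — see `inst/extdata/demo_config.yaml` and
the thin CLI wrapper `inst/scripts/lqrg-run.R`.

The methods vignette (`vignettes/tcp-modelling.Rmd`) documents the model
assumptions, unit conventions, reconstruction choices and the limits of
what synthetic-cohort validation can show.

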