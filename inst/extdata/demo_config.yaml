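# Demo pipeline configuration: a small simulated three-group cohort and a
# light fitting budget so the whole run finishes in seconds. Increase group
# sizes, n_starts and max_iter for production analyses.
cohort:
  spec:
    volume_cv: 0.5
    horizon_min: 5.4
    horizon_max: 64.3
fit:
  models: [lq, lqrg]
  free:
    lq: [alpha, beta, rho]
    lqrg: [alpha, beta, sigma2, delta, rho]
  control:
    max_iter: 120
    patience: 20
    n_starts: 2
  loo: false
curve_times:
  from: 0
  to: 70
  by: 1
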