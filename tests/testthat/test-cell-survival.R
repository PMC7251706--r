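test_that("single acute fraction before regrowth delay matches hand algebra", {
  # G = 1, T = 0 < T_k, Gompertz term 0 at t = 0:
  # ln SF = -alpha*d - beta*d^2 + 0.5*sigma2*d^2
  p <- lqrg_params()
  s <- uniform_schedule(1, 8, weekday_only = FALSE)
  expect_equal(surviving_fraction(p, s, 0),
               exp(-p$alpha * 8 - p$beta * 64 + 0.5 * p$sigma2 * 64),
               tolerance = 1e-12)
  expect_error(surviving_fraction(p, s, -1), "non-negative")
})

test_that("extended-model exponent matches a term-by-term oracle", {
  p <- lqrg_params()
  s <- group_schedule(64.07, 2.4)
  t_h <- months_to_hours(12)
  D <- total_dose(s)
  expo <- -p$alpha * D -
    p$beta * lea_catcheside_g(s, p$tau_R) * D^2 +
    0.5 * p$sigma2 * lea_catcheside_g(s, p$tau_S) * D^2 +
    log(2) * max(0, overall_time(s) / 24 - p$T_k / 24) / p$tau_P +
    (log(2) * (t_h / 24) / p$tau_P)^p$delta
  expect_equal(surviving_fraction(p, s, t_h), exp(expo), tolerance = 1e-12)
})

test_that("extended model collapses to the classical baseline in the limit", {
  # sigma2 -> 0, delta = 1, tau_R -> 0 (complete repair) with matched
  # parameters reproduces the classical LQ surviving fraction
  lq <- lq_params()
  lqrg_lim <- lqrg_params(alpha = lq$alpha, beta = lq$beta, sigma2 = 1e-30,
                          tau_R = 1e-4, tau_S = 1e-4, tau_P = lq$tau_P,
                          T_k = lq$T_k, delta = 1, rho = lq$rho)
  s <- group_schedule(62.92, 2.1)
  for (t_h in months_to_hours(c(0, 6, 24)))
    expect_equal(surviving_fraction(lqrg_lim, s, t_h),
                 surviving_fraction(lq, s, t_h), tolerance = 1e-8)
})

test_that("classical baseline uses complete-repair G and is log-linear in t", {
  lq <- lq_params()
  s <- group_schedule(62.92, 2.1)   # 30 fractions: G = 0.033 to 3 decimals
  expect_equal(round(complete_repair_g(s), 3), 0.033)
  D <- total_dose(s)
  d <- fraction_size(s)
  # quadratic term is -beta*D*d, i.e. G = 1/n
  expect_equal(log(surviving_fraction(lq, s, 0)),
               -lq$alpha * D - lq$beta * D * d +
                 log(2) * max(0, overall_time(s) / 24 - lq$T_k / 24) / lq$tau_P,
               tolerance = 1e-12)
  # doubling elapsed time adds exactly ln2 * dt / tau_P to log-SF
  t1 <- months_to_hours(10); t2 <- 2 * t1
  expect_equal(log(surviving_fraction(lq, s, t2)) -
                 log(surviving_fraction(lq, s, t1)),
               log(2) * hours_to_days(t1) / lq$tau_P, tolerance = 1e-12)
})

test_that("SF is increasing in elapsed time and decreasing in dose", {
  p <- lqrg_params()
  s <- group_schedule(64.07, 2.4)
  sf <- surviving_fraction(p, s, months_to_hours(c(1, 6, 12, 24, 48)))
  expect_true(all(diff(sf) > 0))
  sf_D <- vapply(c(0.5, 0.8, 1, 1.2), function(scale) {
    ss <- fx_schedule(s$start_times, s$doses * scale)
    surviving_fraction(p, ss, 0)
  }, 1)
  expect_true(all(diff(sf_D) < 0))
})

test_that("BED is consistent with SF and ordered across the groups", {
  p <- lqrg_params()
  # classical single-dose limit: sigma2 negligible, T <= T_k
  p0 <- lqrg_params(sigma2 = 1e-30)
  s1 <- uniform_schedule(1, 10, weekday_only = FALSE)
  expect_equal(bed_lqrg(p0, s1), 10 + p0$beta * 100 / p0$alpha,
               tolerance = 1e-10)
  # -ln SF(0) = alpha * BED for any schedule
  beds <- vapply(names(grp_defs), function(g) {
    s <- group_schedule(grp_defs[[g]]$dose, grp_defs[[g]]$d)
    b <- bed_lqrg(p, s)
    expect_equal(-log(surviving_fraction(p, s, 0)), p$alpha * b,
                 tolerance = 1e-10)
    b
  }, 1)
  expect_true(beds[["A"]] < beds[["B"]])
  expect_true(beds[["B"]] < beds[["C"]])
})

test_that("beta_eff recasts the quadratic terms exactly", {
  p <- lqrg_params()
  # acute single fraction with negligible resensitization: beta_eff = beta
  p0 <- lqrg_params(sigma2 = 1e-30)
  s1 <- uniform_schedule(1, 5, weekday_only = FALSE)
  expect_equal(beta_eff(p0, s1)$beta_eff, p0$beta, tolerance = 1e-10)
  # recast identity -beta_eff*D*d = -beta*G_R*D^2 + 0.5*sigma2*G_S*D^2
  set.seed(3)
  for (i in 1:20) {
    s <- uniform_schedule(sample(2:35, 1), runif(1, 1, 4),
                          interval = runif(1, 6, 48), weekday_only = FALSE)
    D <- total_dose(s); d <- fraction_size(s)
    be <- beta_eff(p, s)$beta_eff
    expect_equal(-be * D * d,
                 -p$beta * lea_catcheside_g(s, p$tau_R) * D^2 +
                   0.5 * p$sigma2 * lea_catcheside_g(s, p$tau_S) * D^2,
                 tolerance = 1e-10)
  }
  # dominant resensitization flags the ratio as undefined, no exception
  p_big <- lqrg_params(sigma2 = 10)
  res <- beta_eff(p_big, uniform_schedule(10, 2))
  expect_false(res$valid)
  expect_true(is.na(res$alpha_over_beta_eff))
})

test_that("packaged defaults match the fitted parameter table", {
  p <- lqrg_params()
  expect_equal(p$alpha, 0.06691)
  expect_equal(p$tau_R, 6.32)
  expect_equal(p$tau_P, 84.55)
  expect_equal(hours_to_days(p$T_k), 22.2, tolerance = 0.05)
  q <- lq_params()
  expect_equal(q$alpha, 0.3932)
  expect_equal(q$alpha / q$beta, 9.2, tolerance = 0.05)
})
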