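test_that("MAE cost has its textbook properties", {
  p <- lqrg_params()
  data <- fitdata_from_model(p)
  # model-generated data: zero cost at the generating parameters
  expect_equal(mae_cost(p, data), 0, tolerance = 1e-14)
  # constant offset epsilon on every sample costs exactly epsilon
  eps <- 0.037
  data_off <- data
  data_off$groups <- lapply(data$groups, function(g) {
    g$samples$lpfs <- pmax(g$samples$lpfs - eps, g$samples$lpfs * 0 - 1)
    g
  })
  expect_equal(mae_cost(p, tcp_fit_data(data_off$groups)), eps,
               tolerance = 1e-12)
  # invariant to sample ordering
  data_perm <- data
  data_perm$groups <- lapply(data$groups, function(g) {
    g$samples <- g$samples[rev(seq_len(nrow(g$samples))), ]
    g
  })
  expect_equal(mae_cost(p, tcp_fit_data(data_perm$groups)),
               mae_cost(p, data))
})

test_that("generating parameters are optimal on noise-free data", {
  p <- lqrg_params()
  data <- fitdata_from_model(p)
  c0 <- mae_cost(p, data)
  set.seed(99)
  for (i in 1:50) {
    pp <- unclass(p)
    j <- sample(names(pp), 1)
    pp[[j]] <- pp[[j]] * exp(runif(1, -0.5, 0.5))
    if (j == "delta") pp[[j]] <- min(pp[[j]], 1)
    expect_gte(mae_cost(do.call(lqrg_params, pp), data), c0)
  }
})

test_that("fitting is deterministic and recovers a free parameter", {
  p <- lqrg_params()
  data <- fitdata_from_model(p)
  init <- lqrg_params(alpha = 2 * p$alpha)
  ctrl <- fit_control(max_iter = 300, patience = 30, n_starts = 2)
  fit1 <- fit_tcp("lqrg", data, init = init, free = "alpha",
                  control = ctrl, seed = 42)
  fit2 <- fit_tcp("lqrg", data, init = init, free = "alpha",
                  control = ctrl, seed = 42)
  expect_identical(fit1$theta, fit2$theta)
  expect_identical(fit1$cost, fit2$cost)
  expect_true(fit1$converged)
  expect_lt(abs(fit1$params$alpha - p$alpha) / p$alpha, 0.01)
  # invariants of the result object
  expect_gte(fit1$cost, 0)
  expect_equal(length(fit1$free), 1L)
  expect_equal(fit1$n_samples, sum(vapply(data$groups,
                                          function(g) nrow(g$samples), 1L)))
})

test_that("fit validates its inputs", {
  p <- lqrg_params()
  data <- fitdata_from_model(p)
  expect_error(fit_tcp("lqrg", data, init = lqrg_params(alpha = 1),
                       free = "alpha",
                       lower = list(alpha = 2), upper = list(alpha = 3)),
               "within the bounds")
  expect_error(fit_tcp("nonsense", data), "unknown model|must be")
})

test_that("fitting errors match hand arithmetic", {
  expect_equal(fitting_errors(c(0.5, 0.4), c(0.5, 0.4)),
               c(absolute = 0, relative = 0))
  obs <- c(0.8, 0.5, 0.2)
  expect_equal(fitting_errors(1.1 * obs, obs)[["relative"]], 10,
               tolerance = 1e-12)
  # 3-point hand-worked case
  pred <- c(0.9, 0.45, 0.3)
  expect_equal(fitting_errors(pred, obs)[["absolute"]],
               100 * mean(c(0.1, 0.05, 0.1)), tolerance = 1e-12)
  expect_equal(fitting_errors(pred, obs)[["relative"]],
               100 * mean(c(0.1 / 0.8, 0.05 / 0.5, 0.1 / 0.2)),
               tolerance = 1e-12)
  expect_true(is.na(fitting_errors(c(0.1, 0.2), c(0.5, 0))[["relative"]]))
  expect_error(fitting_errors(1:3, 1:2), "equal")
})

test_that("confidence intervals behave sanely", {
  p <- lqrg_params()
  # mild noise so the curvature is finite (noise-free MAE has a kink at 0)
  data <- fitdata_from_model(p)
  set.seed(8)
  data$groups <- lapply(data$groups, function(g) {
    g$samples$lpfs <- pmin(pmax(
      g$samples$lpfs + rnorm(nrow(g$samples), 0, 0.01), 0), 1)
    g
  })
  data <- tcp_fit_data(data$groups)
  fit <- fit_tcp("lqrg", data, init = lqrg_params(alpha = 1.5 * p$alpha),
                 free = "alpha",
                 control = fit_control(max_iter = 300, patience = 30,
                                       n_starts = 1), seed = 1)
  ci <- tcp_confint(fit, data, method = "hessian")
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  expect_true(all(is.finite(c(ci$lower, ci$upper))) && ci$lower > 0)
  # bootstrap is deterministic given a seed (small resample count for speed)
  b1 <- tcp_confint(fit, data, method = "bootstrap", n_boot = 25, seed = 9,
                    control = fit_control(max_iter = 60, patience = 15,
                                          n_starts = 1))
  b2 <- tcp_confint(fit, data, method = "bootstrap", n_boot = 25, seed = 9,
                    control = fit_control(max_iter = 60, patience = 15,
                                          n_starts = 1))
  expect_identical(b1, b2)
  expect_true(b1$lower <= b1$estimate && b1$estimate <= b1$upper)
})

test_that("interval width shrinks toward zero on precise data", {
  p <- lqrg_params()
  narrow <- NULL
  for (noise in c(0.02, 0.002)) {
    data <- fitdata_from_model(p, times = seq(1, 48, by = 1))
    set.seed(5)
    data$groups <- lapply(data$groups, function(g) {
      g$samples$lpfs <- pmin(pmax(
        g$samples$lpfs + rnorm(nrow(g$samples), 0, noise), 0), 1)
      g
    })
    data <- tcp_fit_data(data$groups)
    fit <- fit_tcp("lqrg", data, free = "alpha",
                   control = fit_control(max_iter = 200, patience = 25,
                                         n_starts = 1), seed = 1)
    ci <- tcp_confint(fit, data, method = "hessian")
    narrow <- c(narrow, ci$upper - ci$lower)
  }
  expect_lt(narrow[2], narrow[1])
})
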