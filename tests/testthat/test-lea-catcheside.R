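test_that("a single acute exposure has no protraction sparing (G = 1)", {
  s <- uniform_schedule(1, 8, weekday_only = FALSE)
  for (tau in c(0.1, 1, 6.32, 1000))
    expect_equal(lea_catcheside_g(s, tau), 1)
})

test_that("complete-repair limit gives 1/n for the group schedules", {
  n_exp <- c(A = 30, B = 27, C = 22)
  for (g in names(grp_defs)) {
    s <- group_schedule(grp_defs[[g]]$dose, grp_defs[[g]]$d)
    expect_equal(complete_repair_g(s), 1 / n_exp[[g]], tolerance = 1e-12)
    # pairwise path converges to the same limit for small tau
    expect_equal(lea_catcheside_g(s, 1e-3), 1 / n_exp[[g]], tolerance = 1e-9)
  }
})

test_that("equal-spacing closed form matches its algebraic limits", {
  # complete repair: phi -> 0
  expect_equal(g_equal_fractions(30, 24, 1e-4), 1 / 30, tolerance = 1e-12)
  # no repair: tau -> Inf gives G -> 1
  expect_equal(g_equal_fractions(12, 24, 1e9), 1, tolerance = 1e-6)
  expect_equal(g_equal_fractions(1, 24, 6.32), 1)
})

test_that("numerical pairwise path agrees with the closed form to 1e-10", {
  s <- uniform_schedule(30, 2, weekday_only = FALSE)
  expect_equal(lea_catcheside_g(s, 6.32), g_equal_fractions(30, 24, 6.32),
               tolerance = 1e-10)
})

test_that("closed-form and numerical paths agree on randomized schedules", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    interval <- runif(1, 4, 72)
    tau <- runif(1, 0.5, 50)
    s <- uniform_schedule(n, runif(1, 0.5, 5), interval = interval,
                          weekday_only = FALSE)
    expect_equal(lea_catcheside_g(s, tau), g_equal_fractions(n, interval, tau),
                 tolerance = 1e-8)
  }
})

test_that("constant-rate delivery matches the continuous-exposure closed form", {
  set.seed(7)
  for (i in 1:20) {
    Td <- runif(1, 0.2, 8)
    tau <- runif(1, 0.3, 12)
    s <- fx_schedule(0, runif(1, 1, 60), durations = Td)
    closed <- (2 * tau / Td) * (1 - (tau / Td) * (1 - exp(-Td / tau)))
    expect_equal(lea_catcheside_g(s, tau), closed, tolerance = 1e-8)
  }
})

test_that("quadrature path matches an independent trapezoid oracle", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(2:4, 1)
    starts <- cumsum(c(0, runif(n - 1, 5, 30)))
    s <- fx_schedule(starts, runif(n, 1, 4), durations = runif(n, 0.5, 3))
    tau <- runif(1, 1, 10)
    # tolerance reflects the oracle's own grid error at the block edges
    expect_equal(lea_catcheside_g(s, tau), trapezoid_g(s, tau),
                 tolerance = 5e-4)
  }
})

test_that("short finite durations converge to the instantaneous limit", {
  tau <- 6.32
  s0 <- uniform_schedule(10, 2)
  s_eps <- fx_schedule(s0$start_times, s0$doses, durations = 1e-4)
  expect_equal(lea_catcheside_g(s_eps, tau), lea_catcheside_g(s0, tau),
               tolerance = 1e-5)
})

test_that("G is monotone in tau and n, and bounded in (0, 1]", {
  taus <- c(0.5, 2, 6.32, 24, 200)
  g_tau <- vapply(taus, function(tau)
    lea_catcheside_g(uniform_schedule(20, 2), tau), 1)
  expect_true(all(diff(g_tau) > 0))
  g_n <- vapply(c(2, 5, 10, 20, 35), function(n)
    lea_catcheside_g(uniform_schedule(n, 2), 6.32), 1)
  expect_true(all(diff(g_n) < 0))
  expect_true(all(g_tau > 0 & g_tau <= 1))
  expect_true(all(g_n > 0 & g_n <= 1))
  expect_error(lea_catcheside_g(uniform_schedule(5, 2), tau = -1), "positive")
})
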