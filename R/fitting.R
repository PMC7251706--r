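#' Assemble fitting data
#'
#' Bundles, per treatment group, the representative schedule, the tumor
#' specification and the (time, LPFS) samples the TCP curve is fitted to.
#'
#' @param groups named list; each element a list with `schedule`
#'   (a [fx_schedule()]), `tumor` (a [tumor_spec()]) and `samples` (data
#'   frame with `time_months`, `lpfs`).
#' @return A `tcp_fit_data` object.
#' @seealso [fit_data_from_cohort()]
#' @export
tcp_fit_data <- function(groups) {
  if (length(groups) == 0L) stop("no groups supplied", call. = FALSE)
  for (g in groups) {
    stopifnot(inherits(g$schedule, "fx_schedule"),
              inherits(g$tumor, "tumor_spec"),
              is.data.frame(g$samples),
              all(c("time_months", "lpfs") %in% names(g$samples)))
    if (nrow(g$samples) == 0L)
      stop("each group needs at least one sample", call. = FALSE)
  }
  structure(list(groups = groups), class = "tcp_fit_data")
}

#' Fitting data from a patient cohort
#'
#' Estimates the Kaplan-Meier LPFS curve per group, samples it at each
#' record's observed time (one sample per patient) and attaches the group's
#' representative schedule and mean GTV volume.
#'
#' @param records patient records (`group`, `gtv_cm3`, `time_months`,
#'   `event`).
#' @param schedules named list of [fx_schedule()], one per group label.
#' @param rho clonogen density used for the tumor specs.
#' @return A `tcp_fit_data` object.
#' @export
fit_data_from_cohort <- function(records, schedules, rho) {
  labs <- sort(unique(records$group))
  if (!all(labs %in% names(schedules)))
    stop("missing schedule for group(s): ",
         paste(setdiff(labs, names(schedules)), collapse = ", "),
         call. = FALSE)
  groups <- lapply(labs, function(lab) {
    rec <- records[records$group == lab, , drop = FALSE]
    list(schedule = schedules[[lab]],
         tumor = tumor_spec(mean(rec$gtv_cm3), rho),
         samples = lpfs_samples(rec))
  })
  names(groups) <- labs
  tcp_fit_data(groups)
}

#' @export
print.tcp_fit_data <- function(x, ...) {
  m <- sum(vapply(x$groups, function(g) nrow(g$samples), 1L))
  cat(sprintf("TCP fitting data: %d group(s), %d pooled samples\n",
              length(x$groups), m))
  invisible(x)
}

n_samples <- function(data) {
  sum(vapply(data$groups, function(g) nrow(g$samples), 1L))
}

#' Model-predicted TCP at the fitting samples
#'
#' @param params parameter object.
#' @param data a `tcp_fit_data`.
#' @return Named list of numeric vectors, one per group.
#' @export
predict_tcp <- function(params, data) {
  lapply(data$groups, function(g) {
    t <- g$samples$time_months
    ord <- order(t)   # samples may arrive in any order
    pred <- numeric(length(t))
    pred[ord] <- tcp_time_curve(params, g$schedule, g$tumor, t[ord])
    pred
  })
}

#' Mean-absolute-error cost
#'
#' The fitting cost: the mean over all pooled samples of |TCP(t_i) -
#' LPFS(t_i)|. All groups' samples are pooled with equal weight; the cost is
#' invariant to sample ordering.
#'
#' @param params parameter object.
#' @param data a `tcp_fit_data`.
#' @return Non-negative scalar.
#' @export
mae_cost <- function(params, data) {
  pred <- predict_tcp(params, data)
  obs <- lapply(data$groups, function(g) g$samples$lpfs)
  mean(abs(unlist(pred) - unlist(obs)))
}

#' Fitting control parameters
#'
#' @param max_iter maximum gradient-descent iterations per start.
#' @param tol convergence: stop when the cost improved by less than `tol`
#'   over the last `patience` iterations.
#' @param patience window (iterations) for the convergence test.
#' @param n_starts number of multi-start initializations (the first is the
#'   supplied `init`; the rest are log-space jitters of it).
#' @param start_spread half-width (natural-log units) of the start jitter.
#' @param step_init initial gradient step length.
#' @param h relative step for central finite-difference gradients.
#' @param max_halvings backtracking line-search depth.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(max_iter = 5000, tol = 1e-7, patience = 50,
                        n_starts = 16, start_spread = 1.0, step_init = 0.1,
                        h = 1e-5, max_halvings = 30) {
  structure(list(max_iter = max_iter, tol = tol, patience = patience,
                 n_starts = n_starts, start_spread = start_spread,
                 step_init = step_init, h = h, max_halvings = max_halvings),
            class = "fit_control")
}

# build a parameter object of the model's class with free entries replaced
.insert_free <- function(model, base, free, values) {
  p <- unclass(base)
  p[free] <- as.list(values)
  do.call(.params_constructor(model), p)
}

#' Fit a TCP model to LPFS data
#'
#' Minimizes the mean absolute error between the model TCP(t) curve and the
#' observed LPFS samples by gradient descent on log-transformed parameters
#' (which enforces positivity), with central finite-difference gradients, a
#' backtracking line search and multi-start initialization. Deterministic
#' for a given seed.
#'
#' @param model `"lq"` or `"lqrg"`.
#' @param data a [tcp_fit_data()].
#' @param init initial parameter object; defaults to the packaged values.
#' @param free character vector of parameter names to optimize; the rest stay
#'   fixed at `init`.
#' @param lower,upper named bounds on the free parameters; default
#'   `init/100` and `init*100` (`delta` is additionally capped at 1).
#' @param control a [fit_control()].
#' @param seed integer master seed for the multi-start jitter.
#' @return A `tcp_fit` with the fitted parameters, final cost, Laplace
#'   log-likelihood, AIC, per-group fitting errors, iteration counts and
#'   convergence flags.
#' @export
fit_tcp <- function(model, data, init = NULL,
                    free = parameter_names(model),
                    lower = NULL, upper = NULL,
                    control = fit_control(), seed = 1L) {
  model <- .model_name(model)
  init <- init %||% .params_constructor(model)()
  free <- match.arg(free, parameter_names(model), several.ok = TRUE)
  init_free <- unlist(unclass(init)[free])
  lo <- init_free / 100
  hi <- init_free * 100
  if (!is.null(lower)) {
    lower <- unlist(lower)
    keep <- intersect(names(lower), free)
    lo[keep] <- lower[keep]
  }
  if (!is.null(upper)) {
    upper <- unlist(upper)
    keep <- intersect(names(upper), free)
    hi[keep] <- upper[keep]
  }
  if ("delta" %in% free) hi["delta"] <- min(hi["delta"], 1)
  if (any(init_free < lo | init_free > hi))
    stop("'init' must lie within the bounds", call. = FALSE)
  llo <- log(lo); lhi <- log(hi)

  obj <- function(theta) {
    p <- tryCatch(.insert_free(model, init, free, exp(theta)),
                  error = function(e) NULL)
    if (is.null(p)) return(Inf)
    val <- tryCatch(mae_cost(p, data), error = function(e) Inf)
    if (!is.finite(val)) Inf else val
  }
  theta0 <- pmin(pmax(log(init_free), llo), lhi)
  if (!is.finite(obj(theta0)))
    stop("cost is not finite at 'init'", call. = FALSE)

  # multi-start: screen a seeded pool of log-space jitters around the
  # initial point and descend from the best-scoring candidates (the MAE
  # surface can be plateau-valley shaped, so descent alone may stall far
  # from the optimum)
  set.seed(as.integer(seed %% .Machine$integer.max))
  starts <- list(theta0)
  if (control$n_starts > 1L) {
    n_pool <- max(32L, 4L * control$n_starts)
    pool <- replicate(n_pool, pmin(pmax(
      theta0 + stats::runif(length(theta0), -control$start_spread,
                            control$start_spread), llo), lhi),
      simplify = FALSE)
    pool_cost <- vapply(pool, obj, 1)
    keep <- order(pool_cost)[seq_len(control$n_starts - 1L)]
    starts <- c(starts, pool[keep])
  }

  runs <- lapply(starts, function(th)
    .gradient_descent(obj, th, llo, lhi, control))
  costs <- vapply(runs, function(r) r$cost, 1)
  best <- runs[[which.min(costs)]]

  params_hat <- .insert_free(model, init, free, exp(best$theta))
  m <- n_samples(data)
  ll <- loglik_from_mae(best$cost, m)
  pred <- predict_tcp(params_hat, data)
  errs <- lapply(names(data$groups), function(g)
    fitting_errors(pred[[g]], data$groups[[g]]$samples$lpfs))
  names(errs) <- names(data$groups)

  structure(list(
    model = model, params = params_hat, free = free,
    theta = best$theta, lower = lo, upper = hi,
    cost = best$cost, loglik = ll,
    aic = aic_from_loglik(length(free), ll),
    n_samples = m, group_errors = errs,
    iterations = best$iterations, converged = best$converged,
    start_costs = costs, seed = as.integer(seed),
    init = init, control = control), class = "tcp_fit")
}

.gradient_descent <- function(obj, theta, llo, lhi, control) {
  f_cur <- obj(theta)
  k <- length(theta)
  step <- control$step_init
  hist <- f_cur
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    g <- numeric(k)
    for (j in seq_len(k)) {
      hj <- control$h * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- theta[j] + hj
      tm <- theta; tm[j] <- theta[j] - hj
      g[j] <- (obj(tp) - obj(tm)) / (2 * hj)
    }
    gn2 <- sum(g^2)
    if (!is.finite(gn2) || gn2 < 1e-20) { converged <- TRUE; break }
    s <- step
    improved <- FALSE
    for (half in seq_len(control$max_halvings)) {
      cand <- pmin(pmax(theta - s * g, llo), lhi)
      f_new <- obj(cand)
      if (is.finite(f_new) && f_new <= f_cur - 1e-4 * s * gn2) {
        improved <- TRUE
        break
      }
      s <- s / 2
    }
    if (!improved) { converged <- TRUE; break }  # no descent direction left
    theta <- cand
    f_cur <- f_new
    step <- min(s * 2, 10)
    hist <- c(hist, f_cur)
    if (it >= control$patience &&
        hist[length(hist) - control$patience] - f_cur < control$tol) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, cost = f_cur, iterations = it, converged = converged)
}

#' @export
print.tcp_fit <- function(x, ...) {
  cat(sprintf("TCP fit (%s): %d free parameter(s), %d samples\n",
              toupper(x$model), length(x$free), x$n_samples))
  cat(sprintf("  MAE = %.5g  logLik = %.4g  AIC = %.4g  converged: %s\n",
              x$cost, x$loglik, x$aic, x$converged))
  for (nm in x$free)
    cat(sprintf("  %-8s %s\n", nm, format(x$params[[nm]], digits = 5)))
  invisible(x)
}

#' Absolute and relative fitting errors
#'
#' Average absolute error 100 * mean|p_i - o_i| and average relative error
#' 100 * mean(|p_i - o_i| / o_i), both in percent. The relative error is
#' undefined (NA) when any observed value is zero.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return Named vector `c(absolute = , relative = )`, percent.
#' @export
fitting_errors <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0L)
    stop("'predicted' and 'observed' must be equal non-zero length",
         call. = FALSE)
  abs_err <- 100 * mean(abs(predicted - observed))
  rel_err <- if (any(observed == 0)) NA_real_ else
    100 * mean(abs(predicted - observed) / observed)
  c(absolute = abs_err, relative = rel_err)
}

#' Confidence intervals for fitted parameters
#'
#' `"hessian"`: normal-theory intervals from the curvature of the Laplace
#' surrogate log-likelihood at the optimum, computed in log-parameter space
#' and exponentiated (so bounds stay positive). Falls back to the bootstrap
#' with a message when the curvature is singular. `"bootstrap"`: percentile
#' intervals over seeded case resamples of the fitting samples within each
#' group, refitting from the fitted optimum.
#'
#' @param fit a `tcp_fit`.
#' @param data the `tcp_fit_data` the model was fitted to.
#' @param method `"hessian"` or `"bootstrap"`.
#' @param level confidence level.
#' @param n_boot bootstrap resamples (>= 200 recommended).
#' @param seed integer seed (bootstrap).
#' @param control refit control for the bootstrap; defaults to a short
#'   warm-started descent.
#' @return Data frame with `parameter`, `estimate`, `lower`, `upper`,
#'   `method`.
#' @export
tcp_confint <- function(fit, data, method = c("hessian", "bootstrap"),
                        level = 0.95, n_boot = 200, seed = 1L,
                        control = fit_control(max_iter = 200, patience = 20,
                                              n_starts = 1)) {
  method <- match.arg(method)
  if (!isTRUE(fit$converged))
    stop("confidence intervals require a converged fit", call. = FALSE)
  est <- exp(fit$theta)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "hessian") {
    m <- n_samples(data)
    negll <- function(theta) {
      p <- tryCatch(.insert_free(fit$model, fit$init, fit$free, exp(theta)),
                    error = function(e) NULL)
      if (is.null(p)) return(Inf)
      mae <- mae_cost(p, data)
      m * (log(2 * max(mae, 1e-12)) + 1)
    }
    H <- tryCatch(stats::optimHess(fit$theta, negll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0)) {
      message("singular curvature; falling back to bootstrap intervals")
      return(tcp_confint(fit, data, "bootstrap", level, n_boot, seed, control))
    }
    se <- sqrt(diag(V))
    return(data.frame(parameter = fit$free, estimate = est,
                      lower = exp(fit$theta - z * se),
                      upper = exp(fit$theta + z * se),
                      method = "hessian", row.names = NULL))
  }
  # bootstrap: case-resample the samples within each group, refit warm-started
  set.seed(as.integer(seed %% .Machine$integer.max))
  boot_seeds <- sample.int(2^31 - 2, n_boot)
  draws <- matrix(NA_real_, n_boot, length(fit$free))
  for (b in seq_len(n_boot)) {
    set.seed(boot_seeds[b])
    groups_b <- lapply(data$groups, function(g) {
      idx <- sample.int(nrow(g$samples), replace = TRUE)
      g$samples <- g$samples[sort(idx), , drop = FALSE]
      g
    })
    refit <- tryCatch(
      fit_tcp(fit$model, tcp_fit_data(groups_b), init = fit$params,
              free = fit$free,
              lower = stats::setNames(as.list(fit$lower), fit$free),
              upper = stats::setNames(as.list(fit$upper), fit$free),
              control = control, seed = boot_seeds[b]),
      error = function(e) NULL)
    if (!is.null(refit)) draws[b, ] <- exp(refit$theta)
  }
  qs <- apply(draws, 2, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  data.frame(parameter = fit$free, estimate = est,
             lower = pmin(qs[1L, ], est), upper = pmax(qs[2L, ], est),
             method = "bootstrap", row.names = NULL)
}
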