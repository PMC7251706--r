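#' Maximum log-likelihood implied by an MAE fit
#'
#' Under independent Laplace (double-exponential) residuals the MAE
#' minimizer is the exact maximum-likelihood estimator, and the maximized
#' log-likelihood of m samples is
#' \deqn{LL = -m\,(\ln(2\,MAE) + 1).}
#' This is the link through which minimizing the mean absolute error is
#' equivalent to maximizing a log-likelihood.
#'
#' @param mae mean absolute error, >= 0.
#' @param m number of samples, >= 1.
#' @return Log-likelihood; `+Inf` with attribute `degenerate = TRUE` when
#'   `mae` is exactly zero.
#' @examples
#' loglik_from_mae(1 / (2 * exp(1)), 103) # 0
#' @export
loglik_from_mae <- function(mae, m) {
  if (mae < 0) stop("'mae' must be non-negative", call. = FALSE)
  if (m < 1) stop("'m' must be >= 1", call. = FALSE)
  if (mae == 0) return(structure(Inf, degenerate = TRUE))
  -m * (log(2 * mae) + 1)
}

#' Akaike information criterion
#'
#' AIC = 2k - 2 LL; lower is better.
#'
#' @param k number of free parameters, >= 0.
#' @param loglik maximized log-likelihood.
#' @return AIC value.
#' @examples
#' aic_from_loglik(5, 1.07)     #  7.86
#' aic_from_loglik(11, 117.14)  # -212.28
#' @export
aic_from_loglik <- function(k, loglik) {
  if (k < 0) stop("'k' must be non-negative", call. = FALSE)
  2 * k - 2 * loglik
}

#' Leave-one-out cross-validated prediction accuracy
#'
#' For each pooled (time, LPFS) sample i, the model is refitted on the
#' remaining samples (warm-started from the full-data fit) and used to
#' predict TCP at the left-out time; accuracy is
#' \deqn{100\,(1 - \mathrm{mean}_i\, |pred_i - obs_i| / obs_i)\ \%.}
#' Folds whose refit fails, or whose observed value is zero (relative error
#' undefined), are skipped and counted.
#'
#' @param fit a `tcp_fit` from [fit_tcp()] (supplies model, free mask, warm
#'   start and bounds).
#' @param data the `tcp_fit_data` the model was fitted to.
#' @param control refit control; default a short warm-started descent.
#' @param seed integer seed (passed to the refits).
#' @return List with `accuracy` (%), `n_folds`, `n_skipped`, `flagged`.
#' @export
loo_accuracy <- function(fit, data,
                         control = fit_control(max_iter = 200, patience = 20,
                                               n_starts = 1),
                         seed = 1L) {
  idx <- do.call(rbind, lapply(names(data$groups), function(g)
    data.frame(group = g, row = seq_len(nrow(data$groups[[g]]$samples)),
               stringsAsFactors = FALSE)))
  if (nrow(idx) < 3L) stop("need at least 3 samples", call. = FALSE)
  rel <- rep(NA_real_, nrow(idx))
  skipped <- 0L
  for (i in seq_len(nrow(idx))) {
    g <- idx$group[i]; r <- idx$row[i]
    groups_i <- data$groups
    groups_i[[g]]$samples <- groups_i[[g]]$samples[-r, , drop = FALSE]
    if (nrow(groups_i[[g]]$samples) == 0L) groups_i[[g]] <- NULL
    refit <- tryCatch(
      fit_tcp(fit$model, tcp_fit_data(groups_i), init = fit$params,
              free = fit$free,
              lower = stats::setNames(as.list(fit$lower), fit$free),
              upper = stats::setNames(as.list(fit$upper), fit$free),
              control = control, seed = seed),
      error = function(e) NULL)
    obs <- data$groups[[g]]$samples$lpfs[r]
    if (is.null(refit) || obs <= 0) { skipped <- skipped + 1L; next }
    t_i <- data$groups[[g]]$samples$time_months[r]
    pred <- tcp_time_curve(refit$params, data$groups[[g]]$schedule,
                           data$groups[[g]]$tumor, t_i)
    rel[i] <- abs(pred - obs) / obs
  }
  list(accuracy = 100 * (1 - mean(rel, na.rm = TRUE)),
       n_folds = nrow(idx), n_skipped = skipped, flagged = skipped > 0L)
}

#' Model-quality comparison table
#'
#' Assembles, per fitted model, the sample count, free-parameter count,
#' maximum log-likelihood, AIC and (optionally) leave-one-out prediction
#' accuracy.
#'
#' @param fits named list of `tcp_fit` objects fitted to the same data.
#' @param data the shared `tcp_fit_data`.
#' @param loo logical: also run [loo_accuracy()] per model (slow).
#' @param ... passed to [loo_accuracy()].
#' @return Data frame, one row per model.
#' @export
model_comparison <- function(fits, data, loo = FALSE, ...) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm,
               n_samples = f$n_samples,
               n_parameters = length(f$free),
               loglik = f$loglik,
               aic = f$aic,
               loo_accuracy = if (loo) loo_accuracy(f, data, ...)$accuracy
                              else NA_real_,
               converged = f$converged)
  })
  do.call(rbind, rows)
}
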