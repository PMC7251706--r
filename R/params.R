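#' Radiobiological parameter sets
#'
#' `lqrg_params()` holds the parameter vector of the extended
#' linear-quadratic model with repair, resensitization (redistribution +
#' reoxygenation), delayed regrowth and Gompertzian post-treatment growth;
#' `lq_params()` the classical linear-quadratic baseline. Defaults are the
#' fitted values for locally advanced NSCLC treated with hypo-fractionated
#' SIB-IMRT.
#'
#' @param alpha linear cell-kill coefficient, Gy^-1.
#' @param beta quadratic cell-kill coefficient, Gy^-2.
#' @param sigma2 variance of the post-exposure radiosensitivity distribution,
#'   Gy^-2 (resensitization strength).
#' @param tau_R average DNA repair time, hours.
#' @param tau_S average resensitization time, hours.
#' @param tau_P clonogen doubling time, days.
#' @param T_k delay before tumor regrowth starts, hours.
#' @param delta Gompertz exponent for post-treatment regrowth, in (0, 1].
#' @param rho clonogen density, cm^-3.
#' @param K_cr critical clonogen number below which the tumor is controlled.
#' @param sigma_k Gaussian spread of the clonogen-number distribution.
#'
#' @return A named parameter object (`lqrg_params` / `lq_params`, both
#'   inheriting from `radio_params`).
#' @examples
#' p <- lqrg_params()
#' p$alpha / beta_eff(p, group_schedule(64.07, 2.4))$beta_eff
#' @export
lqrg_params <- function(alpha = 0.06691, beta = 0.1039, sigma2 = 0.1939,
                        tau_R = 6.32, tau_S = 3.04, tau_P = 84.55,
                        T_k = 533.5, delta = 0.2645, rho = 2.296e9,
                        K_cr = 2.367e9, sigma_k = 1.03e9) {
  p <- list(alpha = alpha, beta = beta, sigma2 = sigma2, tau_R = tau_R,
            tau_S = tau_S, tau_P = tau_P, T_k = T_k, delta = delta,
            rho = rho, K_cr = K_cr, sigma_k = sigma_k)
  .check_params(p, delta_bounded = TRUE)
  structure(p, class = c("lqrg_params", "radio_params"))
}

#' @rdname lqrg_params
#' @export
lq_params <- function(alpha = 0.3932, beta = 0.0429, tau_P = 113.8,
                      T_k = 246.06, rho = 7.965e9) {
  p <- list(alpha = alpha, beta = beta, tau_P = tau_P, T_k = T_k, rho = rho)
  .check_params(p, delta_bounded = FALSE)
  structure(p, class = c("lq_params", "radio_params"))
}

.check_params <- function(p, delta_bounded) {
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all parameters must be strictly positive and finite", call. = FALSE)
  if (delta_bounded && (p$delta <= 0 || p$delta > 1))
    stop("'delta' must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.radio_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1L]))
  nm <- names(x)
  for (i in seq_along(x))
    cat(sprintf("  %-8s %s\n", nm[i], format(x[[i]], digits = 6)))
  invisible(x)
}

#' Free parameters of a TCP model
#'
#' The number of parameters estimated when the model is fitted to survival
#' data: 5 for the classical LQ baseline (alpha, beta, tau_P, T_k, rho) and
#' 11 for the extended model.
#'
#' @param model `"lq"` or `"lqrg"`, or a parameter object.
#' @return Integer count (`n_free_parameters`) or character vector of
#'   parameter names (`parameter_names`).
#' @export
n_free_parameters <- function(model) {
  length(parameter_names(model))
}

#' @rdname n_free_parameters
#' @export
parameter_names <- function(model) {
  model <- .model_name(model)
  switch(model,
    lq   = c("alpha", "beta", "tau_P", "T_k", "rho"),
    lqrg = c("alpha", "beta", "sigma2", "tau_R", "tau_S", "tau_P", "T_k",
             "delta", "rho", "K_cr", "sigma_k"),
    stop("unknown model '", model, "'", call. = FALSE))
}

.model_name <- function(model) {
  if (inherits(model, "lqrg_params")) return("lqrg")
  if (inherits(model, "lq_params")) return("lq")
  if (is.character(model) && length(model) == 1L &&
      tolower(model) %in% c("lq", "lqrg")) return(tolower(model))
  stop("'model' must be \"lq\", \"lqrg\" or a parameter object", call. = FALSE)
}

.params_constructor <- function(model) {
  switch(.model_name(model), lq = lq_params, lqrg = lqrg_params)
}

#' Read / write parameter JSON
#'
#' @param params a parameter object.
#' @param path file path.
#' @param model `"lq"` or `"lqrg"` (for reading).
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(c(list(model = .model_name(params)), unclass(params)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path, model = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- model %||% obj$model
  obj$model <- NULL
  do.call(.params_constructor(model), obj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
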