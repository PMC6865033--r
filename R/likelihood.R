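#' Log-likelihood of a lifespan sample under a parametric aging model
#'
#' Sums the log density of each observed lifespan under the chosen model.
#' For the network model the per-observation contribution is
#' \deqn{\ln R + (n-1)\ln(1 + t_i/t_0) +
#'       \frac{R t_0}{n}\left(1 - (1 + t_i/t_0)^n\right).}
#' Integer replicative lifespans are treated as continuous observations
#' under the continuous density; no interval-censoring correction is
#' applied.
#'
#' @param model one of `"network"`, `"gompertz"`, `"weibull"`.
#' @param params the matching parameter object ([network_params()],
#'   [gompertz_params()] or [weibull_params()]).
#' @param data a [lifespan_dataset()] or a numeric vector of positive
#'   lifespans.
#' @return The summed log-likelihood. If any observation has zero density
#'   the result is `-Inf` with attribute `zero_density = TRUE` (never an
#'   error).
#' @export
log_likelihood <- function(model, params, data) {
  model <- match.arg(model, c("network", "gompertz", "weibull"))
  t <- as_lifespans(data)
  ll <- switch(model,
    network = {
      stopifnot(inherits(params, "network_params"))
      network_log_density(params, t)
    },
    gompertz = {
      stopifnot(inherits(params, "gompertz_params"))
      R <- params$R; G <- params$G
      log(R) + G * t + (if (G > 0) -(R / G) * expm1(G * t) else -R * t)
    },
    weibull = {
      stopifnot(inherits(params, "weibull_params"))
      stats::dweibull(t, shape = params$shape, scale = params$scale,
                      log = TRUE)
    })
  total <- sum(ll)
  if (is.nan(total)) total <- -Inf
  if (identical(total, -Inf)) attr(total, "zero_density") <- TRUE
  total
}

# ---- internal: likelihood on unconstrained coordinates ----------------------
#
# Each model is optimized on a log-transformed parameter vector so that the
# domain constraints (R, t0 > 0; n > 1; G > 0; shape, scale > 0) hold
# automatically and plain Nelder-Mead can be used.

model_par_names <- function(model) {
  switch(model,
         network = c("R", "t0", "n"),
         gompertz = c("R", "G"),
         weibull = c("shape", "scale"))
}

model_n_par <- function(model) length(model_par_names(model))

theta_to_params <- function(model, theta) {
  switch(model,
         network = new_network_params(exp(theta[1]), exp(theta[2]),
                                      1 + exp(theta[3])),
         gompertz = structure(list(R = exp(theta[1]), G = exp(theta[2])),
                              class = "gompertz_params"),
         weibull = structure(list(shape = exp(theta[1]),
                                  scale = exp(theta[2])),
                             class = "weibull_params"))
}

params_to_theta <- function(model, params) {
  switch(model,
         network = c(log(params$R), log(params$t0), log(params$n - 1)),
         gompertz = c(log(params$R), log(params$G)),
         weibull = c(log(params$shape), log(params$scale)))
}

params_to_estimate <- function(model, params) {
  est <- unlist(params[model_par_names(model)])
  names(est) <- model_par_names(model)
  est
}

neg_loglik_fn <- function(model, t, n_max = Inf) {
  function(theta) {
    if (any(!is.finite(theta))) return(.Machine$double.xmax)
    params <- theta_to_params(model, theta)
    # the network likelihood has a degenerate ridge toward the Gompertz
    # limit (n, t0 -> Inf at fixed (n-1)/t0); the bound keeps resample fits
    # whose MLE sits at infinity from running away along it
    if (model == "network" && params$n > n_max)
      return(.Machine$double.xmax)
    val <- -log_likelihood(model, params, t)
    if (!is.finite(val)) .Machine$double.xmax else val
  }
}
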