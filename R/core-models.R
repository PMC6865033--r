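#' Survival of one essential module
#'
#' Viability of an essential module whose `n` parallel interactions each
#' decay exponentially at rate `lambda`:
#' \eqn{S_m(t) = 1 - (1 - e^{-\lambda t})^n}. The module survives while at
#' least one interaction is intact.
#'
#' @param lambda interaction decay rate, > 0 (per cell division).
#' @param n number of interactions, integer-like >= 1.
#' @param t age(s), >= 0 (cell divisions); vectorized.
#' @return Viability in `[0, 1]`, same length as `t`.
#' @examples
#' module_survival(lambda = 0.01, n = 3, t = 50)
#' @export
module_survival <- function(lambda, n, t) {
  check_scalar(lambda, "lambda", lower = 0, strict = TRUE)
  check_scalar(n, "n", lower = 1)
  t <- check_time(t)
  1 - (-expm1(-lambda * t))^n
}

#' Hazard of one essential module
#'
#' Mortality rate \eqn{\mu_m(t) = -d\ln S_m/dt} of a module with `n`
#' exponentially decaying interactions:
#' \deqn{\mu_m(t) = \frac{n\lambda e^{-\lambda t}(1-e^{-\lambda t})^{n-1}}
#'       {1-(1-e^{-\lambda t})^n}.}
#' For `n > 1` the hazard starts at 0 (redundancy masks early decay); for
#' `n = 1` it is the constant `lambda` of a single non-aging component.
#'
#' @inheritParams module_survival
#' @return Hazard >= 0, same length as `t`. Errors if the module survival
#'   underflows to zero (hazard no longer representable).
#' @export
module_hazard <- function(lambda, n, t) {
  check_scalar(lambda, "lambda", lower = 0, strict = TRUE)
  check_scalar(n, "n", lower = 1)
  t <- check_time(t)
  q <- -expm1(-lambda * t)        # P(one interaction decayed by t)
  surv <- 1 - q^n
  if (any(surv <= 0))
    stop(sprintf(paste0("module survival underflows to 0 at t = %g ",
                        "(lambda = %g, n = %g); hazard overflows"),
                 t[which(surv <= 0)[1]], lambda, n))
  n * lambda * exp(-lambda * t) * q^(n - 1) / surv
}

#' Early-age approximation of the module hazard
#'
#' For ages well inside the interaction decay scale (`t << 1/lambda`) the
#' module hazard reduces to the power law \eqn{n \lambda^n t^{n-1}}.
#'
#' @inheritParams module_survival
#' @return Approximate hazard, same length as `t`.
#' @export
module_hazard_early <- function(lambda, n, t) {
  check_scalar(lambda, "lambda", lower = 0, strict = TRUE)
  check_scalar(n, "n", lower = 1)
  t <- check_time(t)
  n * lambda^n * t^(n - 1)
}

#' Network hazard, binomial (mechanistic) form
#'
#' Early-age mortality rate of the whole network — `m` essential modules in
#' series, binomial activation `p` per interaction — as an explicit sum over
#' the possible numbers of initially active interactions:
#' \deqn{\mu_{net}(t) = c\,m\,n\,\lambda\,p \sum_{i=1}^{n}
#'   \binom{n-1}{i-1} (p\lambda t)^{i-1} (1-p)^{n-i},}
#' valid for `t << 1/lambda`. By the binomial theorem this sum collapses to
#' the closed form `R (1 + t/t0)^(n-1)` of [network_hazard()] with `t0` and
#' `R` given by [as_network_params()]; the summation form requires integer
#' `n` and is kept as an independent route for cross-checking.
#'
#' @param spec a [mechanistic_spec()].
#' @param t age(s), >= 0; vectorized. A warning is issued when any
#'   `lambda * t > 0.5`, outside the approximation's comfort zone.
#' @return Hazard, same length as `t`.
#' @export
network_hazard_binomial <- function(spec, t) {
  stopifnot(inherits(spec, "mech_spec"))
  t <- check_time(t)
  if (any(spec$lambda * t > 0.5))
    warning(sprintf(paste0("ages with lambda*t > 0.5 requested; the binomial",
                           " network hazard assumes t << 1/lambda = %g"),
                    1 / spec$lambda))
  n <- spec$n; p <- spec$p; lam <- spec$lambda
  i <- seq_len(n)
  coef_i <- choose(n - 1, i - 1) * (1 - p)^(n - i)   # t-free part per term
  # sum_i coef_i * (p*lambda*t)^(i-1), evaluated per age
  s <- vapply(p * lam * t,
              function(x) sum(coef_i * x^(i - 1)),
              numeric(1))
  spec$c * spec$m * n * lam * p * s
}

#' Network hazard, closed form
#'
#' The three-parameter network aging hazard
#' \eqn{\mu_{net}(t) = R (1 + t/t_0)^{n-1}}: strictly increasing for
#' `n > 1`, equal to `R` at birth, and approaching the Gompertz hazard
#' `R exp(Gt)` with `G = (n-1)/t0` when `t << t0`.
#'
#' @param params a [network_params()].
#' @param t age(s), >= 0; vectorized.
#' @return Hazard, same length as `t`.
#' @export
network_hazard <- function(params, t) {
  stopifnot(inherits(params, "network_params"))
  t <- check_time(t)
  params$R * exp((params$n - 1) * log1p(t / params$t0))
}

#' Network survival function
#'
#' \deqn{S_{net}(t) = \exp\left(\frac{R t_0}{n}
#'   \left(1 - (1 + t/t_0)^n\right)\right).}
#' Evaluated in log space; at extreme ages where the inner power overflows,
#' the survival underflows cleanly to 0.
#'
#' @inheritParams network_hazard
#' @return Viability in `[0, 1]`, same length as `t`.
#' @export
network_survival <- function(params, t) {
  stopifnot(inherits(params, "network_params"))
  t <- check_time(t)
  exp(network_log_survival(params, t))
}

network_log_survival <- function(params, t) {
  # (R*t0/n) * (1 - (1 + t/t0)^n), with the power in log space
  grow <- exp(params$n * log1p(t / params$t0))
  (params$R * params$t0 / params$n) * (1 - grow)
}

#' Network lifespan density
#'
#' Probability density of age at death under the network model,
#' \eqn{f_{net}(t) = S_{net}(t)\,\mu_{net}(t)}; integrates to 1 on
#' `[0, Inf)`.
#'
#' @inheritParams network_hazard
#' @return Density >= 0, same length as `t`.
#' @export
network_density <- function(params, t) {
  stopifnot(inherits(params, "network_params"))
  t <- check_time(t)
  exp(network_log_density(params, t))
}

network_log_density <- function(params, t) {
  log(params$R) + (params$n - 1) * log1p(t / params$t0) +
    network_log_survival(params, t)
}

#' Gompertz hazard, survival and density
#'
#' Classical Gompertz mortality \eqn{\mu(t) = R e^{Gt}} with survival
#' \eqn{S(t) = \exp(-(R/G)(e^{Gt} - 1))} for `G > 0` and the exponential
#' limit \eqn{S(t) = e^{-Rt}} for `G = 0` (handled explicitly, no 0/0).
#'
#' @param params a [gompertz_params()].
#' @param t age(s), >= 0; vectorized.
#' @return A list with numeric components `hazard`, `survival`, `density`.
#' @export
gompertz_model <- function(params, t) {
  stopifnot(inherits(params, "gompertz_params"))
  t <- check_time(t)
  R <- params$R; G <- params$G
  hazard <- R * exp(G * t)
  log_surv <- if (G > 0) -(R / G) * expm1(G * t) else -R * t
  survival <- exp(log_surv)
  list(hazard = hazard, survival = survival, density = hazard * survival)
}

#' Weibull hazard, survival and density
#'
#' Shape/scale convention: hazard \eqn{(k/\sigma)(t/\sigma)^{k-1}},
#' survival \eqn{\exp(-(t/\sigma)^k)}. With `shape < 1` the hazard is
#' infinite at `t = 0` (returned as `Inf` with a warning).
#'
#' @param params a [weibull_params()].
#' @param t age(s), >= 0; vectorized.
#' @return A list with numeric components `hazard`, `survival`, `density`.
#' @export
weibull_model <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  t <- check_time(t)
  k <- params$shape; sigma <- params$scale
  if (k < 1 && any(t == 0))
    warning("Weibull hazard is infinite at t = 0 when shape < 1")
  hazard <- (k / sigma) * (t / sigma)^(k - 1)
  survival <- exp(-(t / sigma)^k)
  density <- ifelse(is.infinite(hazard), Inf, hazard * survival)
  list(hazard = hazard, survival = survival, density = density)
}

#' Gompertz coefficient implied by network parameters
#'
#' In the early-age limit `t << t0` the network hazard reduces to the
#' Gompertz form with coefficient \eqn{G = (n - 1)/t_0}. A non-aging system
#' (`G -> 0`) therefore corresponds to `t0 -> Inf`, i.e. extremely reliable
#' interactions.
#'
#' @param params a [network_params()].
#' @return The implied Gompertz coefficient (per cell division).
#' @examples
#' gompertz_coefficient(network_params(0.0047, 56.2, 7.9))
#' @export
gompertz_coefficient <- function(params) {
  stopifnot(inherits(params, "network_params"))
  (params$n - 1) / params$t0
}

#' Phenomenological parameters of a mechanistic network
#'
#' Maps the generating quantities (`m`, `n`, `p`, `lambda`) to the fitted
#' triple (`R`, `t0`, `n`):
#' \deqn{t_0 = \frac{1-p}{p\lambda}, \qquad
#'       R = c\,m\,n\,(p\lambda)^n t_0^{n-1}.}
#' `p = 1` gives `t0 = 0` (a fully wired network has no initial virtual
#' age) and is rejected. The reverse direction is not unique: `m`, `p` and
#' `lambda` enter `R` only through a composite, so recovering `lambda` from
#' a fitted `t0` requires an assumed `p` — see [decay_rate_from_t0()].
#'
#' @param spec a [mechanistic_spec()] with `p < 1`.
#' @return A [network_params()] object (with `n = spec$n`).
#' @export
as_network_params <- function(spec) {
  stopifnot(inherits(spec, "mech_spec"))
  if (spec$p >= 1)
    stop("p = 1 gives t0 = 0: degenerate for the phenomenological model")
  t0 <- (1 - spec$p) / (spec$p * spec$lambda)
  R <- spec$c * spec$m * spec$n * (spec$p * spec$lambda)^spec$n *
    t0^(spec$n - 1)
  new_network_params(R, t0, spec$n)
}

#' Interaction decay rate implied by a fitted t0
#'
#' Inverts `t0 = (1-p)/(p lambda)` under an assumed activation probability
#' `p`, giving the interaction decay rate `lambda` and the mean interaction
#' survival time `1/lambda = p t0/(1-p)` (cell divisions).
#'
#' @param t0 fitted initial virtual age, > 0 (cell divisions).
#' @param p assumed activation probability, in (0, 1).
#' @return A list with `lambda` and `inv_lambda`.
#' @examples
#' decay_rate_from_t0(t0 = 45.4, p = 0.7)$inv_lambda  # about 106 divisions
#' @export
decay_rate_from_t0 <- function(t0, p) {
  check_scalar(t0, "t0", lower = 0, strict = TRUE)
  check_scalar(p, "p", lower = 0, upper = 1, strict = TRUE, strict_upper = TRUE)
  lambda <- (1 - p) / (p * t0)
  list(lambda = lambda, inv_lambda = 1 / lambda)
}
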