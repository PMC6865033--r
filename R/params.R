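#' Phenomenological network aging parameters
#'
#' Bundles the three parameters of the network aging hazard
#' \eqn{\mu(t) = R (1 + t/t_0)^{n-1}}: the initial mortality rate `R`
#' (deaths per cell division at birth), the initial virtual age of the
#' system `t0` (IVAS, in cell divisions), and `n`, the apparent average
#' number of lifespan-influencing interactions per essential node.
#'
#' `n` is real-valued here: when estimated from data it is an apparent
#' average over a heterogeneous network, not a wiring count. `n = 1`
#' degenerates to a constant hazard (a non-aging system) and is rejected;
#' use [gompertz_params()] with `G = 0` for that case.
#'
#' @param R initial mortality rate, > 0 (per cell division).
#' @param t0 initial virtual age of the system, > 0 (cell divisions).
#' @param n average lifespan-influencing interactions per essential node,
#'   > 1 (dimensionless).
#' @return An object of class `"network_params"`.
#' @seealso [network_hazard()], [network_survival()], [as_network_params()]
#' @examples
#' network_params(R = 0.0047, t0 = 56.2, n = 7.9)
#' @export
network_params <- function(R, t0, n) {
  check_scalar(R, "R", lower = 0, strict = TRUE)
  check_scalar(t0, "t0", lower = 0, strict = TRUE)
  check_scalar(n, "n", lower = 1, strict = TRUE)
  new_network_params(R, t0, n)
}

# internal constructor: permits n == 1 (needed by the mechanistic mapping,
# where an integer wiring count of 1 is a legal, non-aging network)
new_network_params <- function(R, t0, n) {
  structure(list(R = R, t0 = t0, n = n), class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("Network aging parameters\n")
  cat(sprintf("  R  (initial mortality rate) : %g per division\n", x$R))
  cat(sprintf("  t0 (initial virtual age)    : %g divisions\n", x$t0))
  cat(sprintf("  n  (interactions per node)  : %g\n", x$n))
  cat(sprintf("  implied Gompertz G = (n-1)/t0 = %g per division\n",
              (x$n - 1) / x$t0))
  invisible(x)
}

#' Mechanistic network specification
#'
#' Describes the generating network explicitly: `m` essential modules in
#' series, each holding `n` interaction slots in parallel. An interaction is
#' active at birth with probability `p` (binomial activation) and, once
#' active, its strength decays exponentially at constant rate `lambda` — the
#' non-aging component assumption. A module fails when all of its active
#' interactions have decayed; failure of any module kills the cell. The
#' normalizing constant `c = 1/(1 - (1-p)^n)` conditions on every module
#' being born with at least one active interaction.
#'
#' @param m number of essential modules (integer >= 1).
#' @param n interaction slots per essential node (integer >= 1).
#' @param p probability an interaction is active at t = 0, in (0, 1].
#' @param lambda decay rate of interaction strength, > 0 (per cell division).
#' @return An object of class `"mech_spec"` with the derived constant `c`.
#' @seealso [network_hazard_binomial()], [simulate_mechanistic()],
#'   [as_network_params()]
#' @examples
#' mechanistic_spec(m = 1000, n = 7, p = 0.7, lambda = 0.005)
#' @export
mechanistic_spec <- function(m, n, p, lambda) {
  check_count(m, "m")
  check_count(n, "n")
  check_scalar(p, "p", lower = 0, upper = 1, strict = TRUE, strict_upper = FALSE)
  check_scalar(lambda, "lambda", lower = 0, strict = TRUE)
  cc <- 1 / (1 - (1 - p)^n)
  structure(list(m = as.integer(m), n = as.integer(n), p = p,
                 lambda = lambda, c = cc),
            class = "mech_spec")
}

#' @export
print.mech_spec <- function(x, ...) {
  cat("Mechanistic network specification\n")
  cat(sprintf("  m = %d essential modules, n = %d interactions per node\n",
              x$m, x$n))
  cat(sprintf("  activation p = %g, decay rate lambda = %g per division\n",
              x$p, x$lambda))
  cat(sprintf("  normalizing constant c = %g\n", x$c))
  invisible(x)
}

#' Gompertz mortality parameters
#'
#' The classical two-parameter description of aging:
#' \eqn{\mu(t) = R e^{Gt}} with initial mortality rate `R` (lifespan
#' potential at birth) and Gompertz coefficient `G` (rate of aging, per
#' unit time). `G = 0` is the non-aging exponential-decay case, as seen in
#' bacterial phages.
#'
#' @param R initial mortality rate, > 0.
#' @param G Gompertz coefficient, >= 0 (1/time).
#' @return An object of class `"gompertz_params"`.
#' @export
gompertz_params <- function(R, G) {
  check_scalar(R, "R", lower = 0, strict = TRUE)
  check_scalar(G, "G", lower = 0, strict = FALSE)
  structure(list(R = R, G = G), class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz parameters: R = %g, G = %g%s\n", x$R, x$G,
              if (x$G == 0) " (non-aging limit)" else ""))
  invisible(x)
}

#' Weibull parameters (shape/scale)
#'
#' Standard shape/scale parameterization with hazard
#' \eqn{(k/\sigma)(t/\sigma)^{k-1}}; used only as a comparison model in AIC
#' tables.
#'
#' @param shape shape k, > 0 (dimensionless).
#' @param scale scale sigma, > 0 (time units).
#' @return An object of class `"weibull_params"`.
#' @export
weibull_params <- function(shape, scale) {
  check_scalar(shape, "shape", lower = 0, strict = TRUE)
  check_scalar(scale, "scale", lower = 0, strict = TRUE)
  structure(list(shape = shape, scale = scale), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull parameters: shape = %g, scale = %g\n",
              x$shape, x$scale))
  invisible(x)
}

#' Per-strain lifespan dataset
#'
#' A labelled vector of per-cell replicative lifespans (cell divisions
#' completed before senescence) for one strain. Lifespans must be positive
#' and finite; right-censored observations are not supported (replicative
#' lifespan assays follow every mother cell to death).
#'
#' @param strain strain label (length-1 character).
#' @param lifespans numeric vector of positive, finite lifespans.
#' @return An object of class `"lifespan_dataset"`.
#' @export
lifespan_dataset <- function(strain, lifespans) {
  if (!is.character(strain) || length(strain) != 1L || is.na(strain))
    stop("`strain` must be a single, non-missing character label")
  lifespans <- as.numeric(lifespans)
  if (length(lifespans) == 0L)
    stop("`lifespans` must be non-empty")
  if (anyNA(lifespans) || any(!is.finite(lifespans)))
    stop("`lifespans` must be finite and non-missing")
  if (any(lifespans <= 0))
    stop("all lifespans must be > 0 (right-censoring is not supported)")
  structure(list(strain = strain, lifespans = lifespans),
            class = "lifespan_dataset")
}

#' @export
print.lifespan_dataset <- function(x, ...) {
  cat(sprintf("Lifespan dataset '%s': %d cells, mean RLS %.2f (range %g-%g)\n",
              x$strain, length(x$lifespans), mean(x$lifespans),
              min(x$lifespans), max(x$lifespans)))
  invisible(x)
}

#' @export
length.lifespan_dataset <- function(x) length(x$lifespans)

# ---- shared argument checks -------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict = FALSE, strict_upper = strict) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name))
  lo_ok <- if (strict) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g is outside its domain (%s%g, %g%s)", name, x,
                 if (strict) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"))
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower)
    stop(sprintf("`%s` must be an integer >= %d", name, lower))
  invisible(as.integer(x))
}

check_time <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || anyNA(t))
    stop("`t` must be numeric and non-missing")
  if (any(t < 0))
    stop("`t` must be >= 0 (age in cell divisions)")
  invisible(as.numeric(t))
}

as_lifespans <- function(data) {
  if (inherits(data, "lifespan_dataset")) return(data$lifespans)
  if (is.numeric(data)) {
    if (length(data) == 0L || anyNA(data) || any(!is.finite(data)) ||
        any(data <= 0))
      stop("lifespans must be positive, finite and non-missing")
    return(as.numeric(data))
  }
  stop("`data` must be a lifespan_dataset or a numeric vector of lifespans")
}
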