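#' Sample lifespans from the closed-form network model
#'
#' Exact inverse-CDF sampling from the network survival function: with
#' `u ~ Uniform(0, 1)`,
#' \deqn{t = t_0\left[\left(1 - \frac{n \ln u}{R t_0}\right)^{1/n} -
#'       1\right]}
#' has survival function \eqn{S_{net}}. `u = 1` maps to `t = 0` and
#' `u -> 0` to `t -> Inf`.
#'
#' @param params a [network_params()].
#' @param n_samples number of cells to draw, >= 1.
#' @param seed optional integer seed.
#' @param strain label for the resulting dataset (default `"simulated"`).
#' @return A [lifespan_dataset()] of `n_samples` lifespans.
#' @examples
#' sample_closed_form(network_params(0.0047, 56.2, 7.9), 5, seed = 1)
#' @export
sample_closed_form <- function(params, n_samples, seed = NULL,
                               strain = "simulated") {
  stopifnot(inherits(params, "network_params"))
  check_count(n_samples, "n_samples")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n_samples)
  t <- quantile_closed_form(params, u)
  lifespan_dataset(strain, t)
}

# inverse survival function: t such that S_net(t) = u
quantile_closed_form <- function(params, u) {
  with(params, t0 * (exp(log1p(-n * log(u) / (R * t0)) / n) - 1))
}

#' Simulate cell-by-cell failure of the mechanistic network
#'
#' Draws lifespans by running the generating process itself, with no
#' appeal to the closed-form hazard. Per cell: each of the `m` essential
#' modules receives `k` initially active interactions, `k` binomial(n, p)
#' conditioned on `k >= 1` (every module is born functional — this is the
#' sampling counterpart of the normalizing constant `c`). Each active
#' interaction decays after an independent exponential(`lambda`) time; a
#' module fails when its last interaction decays (maximum of `k`
#' exponentials, drawn by inversion from one uniform), and the cell dies
#' at the first module failure (series system).
#'
#' @param spec a [mechanistic_spec()].
#' @param n_cells number of cells to simulate, >= 1.
#' @param seed optional integer seed.
#' @param strain label for the resulting dataset (default `"mechanistic"`).
#' @param chunk cells simulated per block (memory control, default 10000).
#' @return A [lifespan_dataset()] of `n_cells` lifespans.
#' @export
simulate_mechanistic <- function(spec, n_cells, seed = NULL,
                                 strain = "mechanistic", chunk = 10000L) {
  stopifnot(inherits(spec, "mech_spec"))
  check_count(n_cells, "n_cells")
  check_count(chunk, "chunk")
  if (!is.null(seed)) set.seed(seed)
  m <- spec$m; n <- spec$n; p <- spec$p; lam <- spec$lambda
  # active-interaction count per module, conditioned on >= 1
  k_prob <- stats::dbinom(seq_len(n), n, p)
  k_prob <- k_prob / sum(k_prob)
  out <- numeric(n_cells)
  done <- 0L
  while (done < n_cells) {
    nc <- min(chunk, n_cells - done)
    k <- sample.int(n, nc * m, replace = TRUE, prob = k_prob)
    u <- stats::runif(nc * m)
    # module failure = max of k iid exponential(lambda): F(t) = (1-e^-lt)^k
    mod_t <- matrix(-log1p(-u^(1 / k)) / lam, nrow = nc, ncol = m)
    # cell lifespan = earliest module failure
    out[done + seq_len(nc)] <-
      mod_t[cbind(seq_len(nc), max.col(-mod_t, ties.method = "first"))]
    done <- done + nc
  }
  lifespan_dataset(strain, out)
}

#' Empirical hazard curve from observed lifespans
#'
#' Discrete estimator of the mortality rate: ages are binned (default one
#' cell division per bin) and the hazard in each bin is
#' `deaths / (at-risk at bin start * bin width)`. Bins past the last death
#' (at-risk zero) are dropped. A diagnostic for whether mortality
#' accelerates with age, e.g. to check that Gompertz-like aging emerges
#' from a mechanistic simulation of non-aging parts.
#'
#' @param data a [lifespan_dataset()] or numeric lifespan vector; fewer
#'   than 100 observations triggers a warning (the estimator is noisy).
#' @param bin_width bin width in cell divisions, > 0 (default 1).
#' @return A data frame of class `"hazard_curve"` with columns `mid` (bin
#'   midpoint), `hazard`, `deaths` and `at_risk`.
#' @export
empirical_hazard <- function(data, bin_width = 1) {
  t <- as_lifespans(data)
  check_scalar(bin_width, "bin_width", lower = 0, strict = TRUE)
  if (length(t) < 100)
    warning("fewer than 100 observations: empirical hazard will be noisy")
  breaks <- seq(0, max(t) + bin_width, by = bin_width)
  deaths <- tabulate(findInterval(t, breaks, left.open = TRUE),
                     nbins = length(breaks) - 1)
  at_risk <- length(t) - c(0, cumsum(deaths))[seq_along(deaths)]
  keep <- at_risk > 0
  out <- data.frame(mid = (breaks[-length(breaks)] + bin_width / 2)[keep],
                    hazard = deaths[keep] / (at_risk[keep] * bin_width),
                    deaths = deaths[keep],
                    at_risk = at_risk[keep])
  class(out) <- c("hazard_curve", "data.frame")
  out
}

#' Log-linear (Gompertz) trend of an empirical hazard curve
#'
#' Regresses log hazard on age over an early-age window, weighting bins by
#' their death counts. Under Gompertz-like aging the slope estimates the
#' Gompertz coefficient `G` and the intercept estimates `ln R`.
#'
#' @param curve a hazard curve from [empirical_hazard()].
#' @param t_max upper age limit of the window (default `Inf`).
#' @param min_deaths minimum deaths for a bin to enter the regression
#'   (default 1; zero-death bins are always excluded, log of zero).
#' @return A list with `slope` (G estimate), `intercept` (`ln R`
#'   estimate) and `n_bins` used.
#' @export
hazard_trend <- function(curve, t_max = Inf, min_deaths = 1) {
  stopifnot(inherits(curve, "hazard_curve"))
  use <- curve$mid <= t_max & curve$deaths >= max(1, min_deaths)
  if (sum(use) < 3)
    stop("fewer than 3 usable bins in the requested window")
  fit <- stats::lm(log(hazard) ~ mid, data = curve[use, ],
                   weights = curve$deaths[use])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_bins = sum(use))
}
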