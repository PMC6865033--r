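#' Maximum-likelihood fit of an aging model to lifespan data
#'
#' Maximizes [log_likelihood()] over the model's parameter domain using
#' Nelder-Mead on log-transformed coordinates, started from a deterministic
#' moment-matched grid plus optional seed-controlled jittered restarts. The
#' best start wins; ties are broken by first found, so identical inputs,
#' seed and options give bit-identical results.
#'
#' The start grid anchors each candidate to the sample: for the network
#' model `t0` ranges over \{0.5, 1, 2, 4\} times the mean lifespan and `n`
#' over \{2, 4, 8, 16\}, with `R` chosen so the model median matches the
#' sample median; Gompertz and Weibull grids are built the same way.
#'
#' @param model one of `"network"`, `"gompertz"`, `"weibull"`.
#' @param data a [lifespan_dataset()] or numeric vector of positive
#'   lifespans; a warning is issued below 10 observations.
#' @param restarts number of additional jittered restarts around the best
#'   grid start (default 4; requires `seed` to be reproducible).
#' @param tol relative convergence tolerance on the objective (default
#'   1e-8).
#' @param seed optional integer seed for the jittered restarts.
#' @param start optional parameter object used as the only start (used
#'   internally by [bootstrap_fit()]).
#' @param max_iter Nelder-Mead iteration cap per start (default 2000).
#' @param n_max upper bound on the network interaction count `n` (default
#'   30, far above the biological range of 6-8). The network likelihood is
#'   degenerate along the Gompertz-limit ridge `n, t0 -> Inf` at fixed
#'   `(n-1)/t0`; samples whose unbounded MLE sits at infinity would
#'   otherwise send bootstrap summaries to absurd values. A fit with `n`
#'   at the bound means the data are effectively Gompertz.
#' @return An object of class `"aging_fit"`: model name, named `estimate`
#'   vector, `loglik`, `aic` (= 2k - 2 loglik), `convergence` flag and the
#'   number of starts used. Errors (carrying the best point found in the
#'   condition) only if every start fails to reach a finite likelihood.
#' @examples
#' set.seed(1)
#' d <- sample_closed_form(network_params(0.005, 50, 7), 200, seed = 1)
#' fit_mle("network", d, seed = 1)
#' @export
fit_mle <- function(model, data, restarts = 4, tol = 1e-8, seed = NULL,
                    start = NULL, max_iter = 2000, n_max = 30) {
  model <- match.arg(model, c("network", "gompertz", "weibull"))
  t <- as_lifespans(data)
  if (length(t) < 10)
    warning(sprintf("only %d observations: estimates will be unstable",
                    length(t)))
  nll <- neg_loglik_fn(model, t, n_max = n_max)

  starts <- if (is.null(start)) {
    start_grid(model, t)
  } else {
    list(params_to_theta(model, start))
  }

  runs <- lapply(starts, run_nm, nll = nll, tol = tol, max_iter = max_iter)
  best <- pick_best(runs)

  if (restarts > 0 && !is.null(best)) {
    if (!is.null(seed)) set.seed(seed)
    jitter_runs <- lapply(seq_len(restarts), function(i) {
      run_nm(best$par + stats::rnorm(length(best$par), sd = 0.3),
             nll = nll, tol = tol, max_iter = max_iter)
    })
    best <- pick_best(c(list(best), jitter_runs))
  }

  n_starts <- length(starts) + if (is.null(best)) 0L else restarts
  if (is.null(best)) {
    cond <- structure(
      class = c("netaging_nonconvergence", "error", "condition"),
      list(message = sprintf("all %d starts failed for the %s model",
                             n_starts, model),
           call = sys.call(), best_found = runs))
    stop(cond)
  }

  params <- theta_to_params(model, best$par)
  k <- model_n_par(model)
  loglik <- -best$value
  structure(list(model = model,
                 estimate = params_to_estimate(model, params),
                 params = params,
                 loglik = loglik,
                 aic = 2 * k - 2 * loglik,
                 k = k,
                 convergence = best$convergence == 0,
                 n_starts = n_starts,
                 n_obs = length(t),
                 strain = if (inherits(data, "lifespan_dataset"))
                   data$strain else NA_character_),
            class = "aging_fit")
}

run_nm <- function(theta0, nll, tol, max_iter) {
  v0 <- nll(theta0)
  if (!is.finite(v0) || v0 >= .Machine$double.xmax) return(NULL)
  res <- tryCatch(
    stats::optim(theta0, nll, method = "Nelder-Mead",
                 control = list(maxit = max_iter, reltol = tol)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) ||
      res$value >= .Machine$double.xmax) return(NULL)
  res
}

pick_best <- function(runs) {
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) return(NULL)
  runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
}

# deterministic, moment-matched start grid on transformed coordinates
start_grid <- function(model, t) {
  mt <- mean(t); md <- stats::median(t)
  switch(model,
    network = {
      grid <- expand.grid(t0 = c(0.5, 1, 2, 4) * mt, n = c(2, 4, 8, 16))
      lapply(seq_len(nrow(grid)), function(i) {
        t0 <- grid$t0[i]; n <- grid$n[i]
        # R such that the model median equals the sample median
        R <- -n * log(0.5) / (t0 * (exp(n * log1p(md / t0)) - 1))
        c(log(R), log(t0), log(n - 1))
      })
    },
    gompertz = {
      lapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(G) {
        R <- -G * log(0.5) / expm1(G * md)
        c(log(R), log(G))
      })
    },
    weibull = {
      lapply(c(1, 2, 4, 8), function(k) {
        sigma <- md / log(2)^(1 / k)
        c(log(k), log(sigma))
      })
    })
}

#' @export
print.aging_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%d cells%s)\n", x$model, x$n_obs,
              if (!is.na(x$strain)) paste0(", strain ", x$strain) else ""))
  print(round(x$estimate, 6))
  cat(sprintf("  loglik = %.3f, AIC = %.2f, converged: %s (%d starts)\n",
              x$loglik, x$aic, x$convergence, x$n_starts))
  invisible(x)
}

#' Fit and compare the network, Gompertz and Weibull models
#'
#' Fits all three models to the same lifespan sample and tabulates
#' log-likelihood and AIC (k = 3 for the network model, 2 for Gompertz and
#' Weibull). A model whose fit fails outright is reported as a missing row
#' rather than aborting the comparison.
#'
#' @inheritParams fit_mle
#' @param ... passed to [fit_mle()] (`restarts`, `tol`, `seed`, ...).
#' @return An object of class `"aging_model_comparison"`: a list with the
#'   individual `fits` and a `table` data frame ordered by AIC (best
#'   first), including `delta_aic` relative to the best model.
#' @export
compare_models <- function(data, ...) {
  models <- c("network", "gompertz", "weibull")
  fits <- lapply(models, function(m)
    tryCatch(fit_mle(m, data, ...), error = function(e) NULL))
  names(fits) <- models
  ok <- !vapply(fits, is.null, logical(1))
  tab <- data.frame(
    model = models[ok],
    k = vapply(fits[ok], `[[`, numeric(1), "k"),
    loglik = vapply(fits[ok], `[[`, numeric(1), "loglik"),
    aic = vapply(fits[ok], `[[`, numeric(1), "aic"),
    converged = vapply(fits[ok], `[[`, logical(1), "convergence"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab), class = "aging_model_comparison")
}

#' @export
print.aging_model_comparison <- function(x, ...) {
  cat("Model comparison (lower AIC is better)\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' Bootstrap uncertainty for a maximum-likelihood fit
#'
#' Resamples the lifespans with replacement `B` times (default 100),
#' refits the model to each resample (started from the point estimate),
#' and summarizes the converged resample fits by per-parameter mean and
#' standard deviation, plus mean and sd of the AIC. Non-converged
#' replicates are dropped and counted, never imputed; more than 50%
#' failures is an error.
#'
#' @inheritParams fit_mle
#' @param B number of bootstrap resamples, >= 1 (default 100).
#' @param seed integer seed controlling both the resampling and the fit
#'   jitter; required for reproducibility.
#' @param .identity if `TRUE`, every "resample" is the original sample
#'   (testing hook for the resampling plumbing).
#' @return An object of class `"aging_boot"` with the point `fit`, `B`,
#'   `n_converged`, named vectors `mean` and `sd`, `aic_mean`, `aic_sd`
#'   and the `seed`.
#' @export
bootstrap_fit <- function(model, data, B = 100, seed = NULL,
                          .identity = FALSE, ...) {
  check_count(B, "B")
  t <- as_lifespans(data)
  point <- fit_mle(model, data, seed = seed, ...)
  if (!is.null(seed)) set.seed(seed)
  idx <- lapply(seq_len(B), function(b) {
    if (.identity) seq_along(t) else
      sample.int(length(t), length(t), replace = TRUE)
  })
  fits <- lapply(idx, function(i)
    tryCatch(fit_mle(model, t[i], restarts = 0, start = point$params, ...),
             error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && f$convergence, fits)
  if (length(fits) < B / 2)
    stop(sprintf("bootstrap for the %s model%s: only %d of %d resample fits converged",
                 model,
                 if (inherits(data, "lifespan_dataset"))
                   paste0(" (strain ", data$strain, ")") else "",
                 length(fits), B))
  est <- do.call(rbind, lapply(fits, `[[`, "estimate"))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(model = model, fit = point, B = B,
                 n_converged = length(fits),
                 mean = colMeans(est),
                 sd = apply(est, 2, sd0),
                 aic_mean = mean(aics),
                 aic_sd = sd0(aics),
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "aging_boot")
}

#' @export
print.aging_boot <- function(x, ...) {
  cat(sprintf("%s model bootstrap (%d/%d converged resamples%s)\n",
              x$model, x$n_converged, x$B,
              if (!is.na(x$seed)) paste0(", seed ", x$seed) else ""))
  tab <- data.frame(mean = x$mean, sd = x$sd)
  print(round(tab, 6))
  cat(sprintf("  AIC %.2f +/- %.2f\n", x$aic_mean, x$aic_sd))
  invisible(x)
}
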