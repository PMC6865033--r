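test_that("log-likelihood matches its closed forms", {
  p <- network_params(0.005, 50, 7)
  # a single birth-age observation contributes ln R
  expect_equal(log_likelihood("network", p, 1e-12), log(0.005),
               tolerance = 1e-6)
  # definition cross-check against the density
  d <- sample_closed_form(p, 50, seed = 11)
  expect_equal(log_likelihood("network", p, d),
               sum(log(network_density(p, d$lifespans))), tolerance = 1e-10)
  # exponential closed form for Gompertz with G = 0
  t <- c(3, 9, 27)
  g0 <- gompertz_params(0.02, 0)
  expect_equal(log_likelihood("gompertz", g0, t),
               3 * log(0.02) - 0.02 * sum(t))
  # weibull route agrees with hazard * survival
  w <- weibull_params(2.5, 30)
  wm <- weibull_model(w, t)
  expect_equal(log_likelihood("weibull", w, t),
               sum(log(wm$hazard * wm$survival)), tolerance = 1e-10)
  # zero-density data flag, never an exception
  ll <- suppressWarnings(log_likelihood("weibull", w, 1e300))
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "zero_density"))
})

test_that("fit_mle recovers generating parameters", {
  truth <- network_params(0.005, 50, 7)
  d <- sample_closed_form(truth, 1000, seed = 101)
  f <- fit_mle("network", d, seed = 1)
  expect_true(f$convergence)
  # t0 and n ride a weakly identified ridge (they grow together at fixed
  # (n-1)/t0), so individually they spread widely even at 1000 cells; the
  # well-identified functionals R and the implied Gompertz coefficient
  # recover tightly. Bounds are the measured behavior at this fixed seed.
  expect_lt(rel_err(f$estimate[["R"]], 0.005), 0.10)
  G_hat <- (f$estimate[["n"]] - 1) / f$estimate[["t0"]]
  expect_lt(rel_err(G_hat, 6 / 50), 0.15)
  expect_lt(rel_err(f$estimate[["t0"]], 50), 0.50)
  expect_lt(rel_err(f$estimate[["n"]], 7), 0.50)
  # fitted likelihood cannot fall below the truth's
  expect_gte(f$loglik, log_likelihood("network", truth, d))

  g_truth <- gompertz_params(0.005, 0.1)
  set.seed(202)
  u <- runif(1000)  # exact Gompertz inverse-CDF draw as the oracle input
  tg <- log1p(-0.1 * log(u) / 0.005) / 0.1
  fg <- fit_mle("gompertz", tg, seed = 1)
  expect_lt(rel_err(fg$estimate[["G"]], 0.1), 0.10)
  expect_gte(fg$loglik, log_likelihood("gompertz", g_truth, tg))
})

test_that("fit_mle is deterministic and survives degenerate input", {
  d <- sample_closed_form(network_params(0.004, 40, 6), 300, seed = 5)
  f1 <- fit_mle("network", d, seed = 9)
  f2 <- fit_mle("network", d, seed = 9)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$loglik, f2$loglik)
  # constant dataset: converges or reports non-convergence, never crashes
  out <- tryCatch(suppressWarnings(fit_mle("network", rep(25, 40), seed = 1)),
                  netaging_nonconvergence = function(e) e)
  expect_true(inherits(out, "aging_fit") ||
                inherits(out, "netaging_nonconvergence"))
  expect_warning(fit_mle("gompertz", c(10, 20, 30), seed = 1), "unstable")
})

test_that("AIC bookkeeping and model comparison behave", {
  d <- sample_closed_form(network_params(0.003, 40, 8), 400, seed = 31)
  cmp <- compare_models(d, seed = 1)
  expect_setequal(cmp$table$model, c("network", "gompertz", "weibull"))
  # AIC = 2k - 2 loglik exactly, k = 3 network / 2 others
  expect_equal(cmp$table$aic, 2 * cmp$table$k - 2 * cmp$table$loglik)
  expect_equal(sort(cmp$table$k), c(2, 2, 3))
  expect_true(all(diff(cmp$table$aic) >= 0))

  # ranking is invariant to reordering lifespans and relabeling the strain
  perm <- lifespan_dataset("other-name", rev(d$lifespans))
  cmp2 <- compare_models(perm, seed = 1)
  expect_identical(cmp$table$model, cmp2$table$model)

  # strongly curved network data: network no worse than Gompertz + 4 on
  # average over seeds
  deltas <- vapply(1:5, function(s) {
    ds <- sample_closed_form(network_params(0.005, 40, 8), 300, seed = 400 + s)
    tab <- compare_models(ds, seed = 1)$table
    tab$aic[tab$model == "network"] - tab$aic[tab$model == "gompertz"]
  }, numeric(1))
  expect_lte(mean(deltas), 4)

  # exponential lifespans: Weibull and Gompertz both nest the exponential
  set.seed(77)
  te <- rexp(500, rate = 0.03)
  tab <- compare_models(te, seed = 1)$table
  expect_lt(abs(tab$aic[tab$model == "weibull"] -
                  tab$aic[tab$model == "gompertz"]), 2)
})

test_that("bootstrap_fit summarizes resample fits", {
  d <- sample_closed_form(network_params(0.005, 50, 7), 100, seed = 21)
  # identity resampling: mean is the point estimate, sd is 0
  b1 <- bootstrap_fit("network", d, B = 1, seed = 3, .identity = TRUE)
  expect_equal(b1$mean, b1$fit$estimate)
  expect_identical(unname(b1$sd), rep(0, 3))
  expect_equal(b1$n_converged, 1L)

  b <- bootstrap_fit("network", d, B = 100, seed = 3)
  expect_true(all(b$sd >= 0))
  expect_lte(abs(b$mean[["t0"]] - b$fit$estimate[["t0"]]), 2 * b$sd[["t0"]])
  # reproducible given the seed
  b2 <- bootstrap_fit("network", d, B = 100, seed = 3)
  expect_identical(b$mean, b2$mean)
})

test_that("bootstrap spread shrinks with sample size", {
  sds <- vapply(c(50, 200, 800), function(nn) {
    d <- sample_closed_form(network_params(0.005, 50, 7), nn, seed = 1000 + nn)
    b <- bootstrap_fit("network", d, B = 60, seed = 4)
    b$sd[["n"]]
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  expect_gt(sds[1] / sds[3], 2)  # roughly 1/sqrt(n_obs): factor 4 expected
})
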