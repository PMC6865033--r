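test_that("parameter constructors enforce their domains", {
  expect_s3_class(network_params(0.005, 50, 7), "network_params")
  expect_error(network_params(0, 50, 7), "domain")
  expect_error(network_params(0.005, -1, 7), "domain")
  expect_error(network_params(0.005, 50, 1), "domain")  # constant-hazard case
  expect_error(network_params(0.005, Inf, 7), "finite")

  expect_error(mechanistic_spec(0, 7, 0.7, 0.01))
  expect_error(mechanistic_spec(10, 7.5, 0.7, 0.01))
  expect_error(mechanistic_spec(10, 7, 0, 0.01), "domain")
  expect_error(mechanistic_spec(10, 7, 0.7, 0), "domain")
  expect_equal(mechanistic_spec(10, 5, 1, 0.01)$c, 1)       # p = 1 => c = 1
  expect_gt(mechanistic_spec(10, 5, 0.3, 0.01)$c, 1)

  expect_equal(gompertz_params(0.01, 0)$G, 0)               # non-aging allowed
  expect_error(gompertz_params(0.01, -0.1), "domain")
  expect_error(weibull_params(0, 10), "domain")
})

test_that("module survival matches its closed form and limits", {
  # n = 1: a single non-aging component, plain exponential decay
  expect_equal(module_survival(0.01, 1, 10), exp(-0.1))
  # nothing has decayed at t = 0
  expect_equal(module_survival(0.01, 5, 0), 1)
  expect_equal(module_survival(2, 3, 0), 1)
  # direct arithmetic oracle
  expect_equal(module_survival(0.01, 3, 50), 1 - (1 - exp(-0.5))^3,
               tolerance = 1e-12)
  # monotone non-increasing in t
  tt <- seq(0, 400, by = 5)
  expect_true(all(diff(module_survival(0.01, 3, tt)) <= 0))
  expect_error(module_survival(-0.01, 3, 5), "domain")
  expect_error(module_survival(0.01, 0, 5), "domain")
  expect_error(module_survival(0.01, 3, -5), ">= 0")
})

test_that("module hazard agrees with the finite-difference of survival", {
  expect_equal(module_hazard(0.01, 5, 0), 0)        # redundancy masks decay
  expect_equal(module_hazard(0.01, 1, c(0, 3, 77)), rep(0.01, 3))
  for (n in c(2, 3, 6)) {
    for (t in c(10, 50, 120)) {
      oracle <- fd_hazard(function(x) module_survival(0.01, n, x), t)
      expect_equal(module_hazard(0.01, n, t), oracle, tolerance = 1e-6)
    }
  }
  # survival underflow is a diagnosed error, not a silent NaN
  expect_error(module_hazard(1, 2, 1e5), "underflows")
})

test_that("early-age module hazard approximates the exact one", {
  expect_equal(module_hazard_early(0.01, 1, 7), 0.01)
  expect_equal(module_hazard_early(0.01, 3, 5), 3 * 1e-6 * 25)
  # within 5% of the exact hazard while lambda*t = 0.01
  for (n in 1:6) {
    t <- 0.01 / 0.01    # lambda*t = 0.01
    gap <- rel_err(module_hazard_early(0.01, n, t),
                   module_hazard(0.01, n, t))
    expect_lt(gap, 0.05)
  }
})

test_that("binomial and closed-form network hazards are identical", {
  # binomial-theorem identity over the full integer grid
  worst <- 0
  for (n in 2:12) for (p in seq(0.1, 0.9, by = 0.2)) {
    for (lambda in c(1e-3, 1e-2)) for (m in c(1, 100, 1000)) {
      spec <- mechanistic_spec(m, n, p, lambda)
      tt <- seq(0, 0.2 / lambda, length.out = 7)
      a <- network_hazard_binomial(spec, tt)
      b <- network_hazard(as_network_params(spec), tt)
      worst <- max(worst, max(abs(a / b - 1)))
    }
  }
  expect_lt(worst, 1e-10)

  # n = 1 limb: constant hazard c*m*lambda*p
  spec1 <- mechanistic_spec(1, 1, 0.5, 0.01)
  expect_equal(network_hazard_binomial(spec1, 10), 2 * 0.5 * 0.01)

  # p = 1: only the fully wired term survives, m copies of the early
  # module hazard
  spec_p1 <- mechanistic_spec(20, 4, 1, 0.01)
  tt <- c(0, 5, 15)
  expect_equal(network_hazard_binomial(spec_p1, tt),
               20 * module_hazard_early(0.01, 4, tt), tolerance = 1e-12)

  expect_warning(network_hazard_binomial(spec_p1, 200), "1/lambda")
})

test_that("closed-form network hazard has the stated shape", {
  p <- by4742()
  expect_equal(network_hazard(p, 0), p$R)
  expect_equal(network_hazard(p, 56.2), 0.0047 * 2^6.9, tolerance = 1e-12)
  tt <- seq(0, 200, by = 2)
  expect_true(all(diff(network_hazard(p, tt)) > 0))
})

test_that("network survival/density satisfy the hazard calculus", {
  p <- by4742()
  expect_equal(network_survival(p, 0), 1)
  expect_equal(network_density(p, 0), p$R)
  t1 <- 26.6
  expect_equal(network_survival(p, t1),
               exp((0.0047 * 56.2 / 7.9) * (1 - (1 + 26.6 / 56.2)^7.9)),
               tolerance = 1e-12)
  # -ln S equals the integral of the hazard
  for (t in c(10, 30, 80)) {
    expect_equal(-log(network_survival(p, t)),
                 quad_cumhaz(function(x) network_hazard(p, x), t),
                 tolerance = 1e-6)
  }
  # density = survival * hazard pointwise, and integrates to 1
  tt <- c(1, 20, 50, 90)
  expect_equal(network_density(p, tt) / network_survival(p, tt),
               network_hazard(p, tt))
  total <- stats::integrate(function(x) network_density(p, x),
                            0, 10 * p$t0, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-4)
  # extreme ages underflow cleanly to 0
  expect_identical(network_survival(p, 1e6), 0)
})

test_that("Gompertz model covers both aging and non-aging regimes", {
  g <- gompertz_params(0.01, 0.1)
  out <- gompertz_model(g, 0)
  expect_equal(out$hazard, 0.01)
  expect_equal(out$survival, 1)
  # G = 0 is exact exponential decay (bacterial-phage case)
  g0 <- gompertz_params(0.01, 0)
  expect_equal(gompertz_model(g0, 100)$survival, exp(-1), tolerance = 1e-12)
  for (t in c(5, 20, 60)) {
    expect_equal(-log(gompertz_model(g, t)$survival),
                 quad_cumhaz(function(x) gompertz_model(g, x)$hazard, t),
                 tolerance = 1e-6)
  }
})

test_that("Weibull model follows the shape/scale convention", {
  w1 <- weibull_params(1, 10)
  expect_equal(weibull_model(w1, c(0, 5, 50))$hazard, rep(0.1, 3))
  w2 <- weibull_params(2, 10)
  expect_equal(weibull_model(w2, 10)$survival, exp(-1))
  total <- stats::integrate(function(x) weibull_model(w2, x)$density,
                            0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_warning(out <- weibull_model(weibull_params(0.5, 10), 0),
                 "infinite")
  expect_identical(out$hazard, Inf)
})

test_that("implied Gompertz coefficient and the early-age limit", {
  expect_equal(gompertz_coefficient(by4742()), 6.9 / 56.2)
  expect_equal(gompertz_coefficient(network_params(0.002, 36, 6.7)), 5.7 / 36)
  expect_lt(gompertz_coefficient(network_params(0.01, 50, 1 + 1e-9)), 1e-9)
  # for t <= t0/20, network hazard matches R*exp(Gt) within 2%
  for (p in list(by4742(), network_params(0.0018, 30.7, 6.1),
                 network_params(0.0034, 74, 7.8))) {
    G <- gompertz_coefficient(p)
    tt <- seq(0, p$t0 / 20, length.out = 9)
    gap <- rel_err(p$R * exp(G * tt), network_hazard(p, tt))
    expect_lt(max(gap), 0.02)
  }
})

test_that("mechanistic-to-phenomenological mapping inverts cleanly", {
  # (1-p)/p = 1 so t0 = 1/lambda
  expect_equal(as_network_params(mechanistic_spec(10, 3, 0.5, 0.01))$t0, 100)
  # R agrees with the t-free limb of the binomial sum at t = 0
  spec <- mechanistic_spec(1000, 7, 0.7, 0.004)
  np <- as_network_params(spec)
  expect_equal(np$R, network_hazard_binomial(spec, 0), tolerance = 1e-12)
  # algebraic round trip through the assumed-p inversion
  back <- decay_rate_from_t0(np$t0, spec$p)
  expect_equal(back$lambda, spec$lambda, tolerance = 1e-12)
  expect_error(as_network_params(mechanistic_spec(10, 3, 1, 0.01)),
               "degenerate")
})

test_that("decay-rate inversion reproduces the assumed-p arithmetic", {
  expect_equal(decay_rate_from_t0(45.4, 0.7)$inv_lambda, 0.7 * 45.4 / 0.3)
  expect_equal(round(decay_rate_from_t0(45.4, 0.7)$inv_lambda), 106)
  expect_equal(decay_rate_from_t0(74, 0.9)$inv_lambda, 666)
  expect_equal(decay_rate_from_t0(33.3, 0.5)$inv_lambda, 33.3)
  expect_error(decay_rate_from_t0(50, 1), "domain")
  expect_error(decay_rate_from_t0(50, 0), "domain")
})

test_that("non-aging chain: G -> 0 forces t0 -> Inf and lambda -> 0", {
  n <- 7
  G_grid <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  t0_grid <- (n - 1) / G_grid
  expect_true(all(diff(t0_grid) > 0))
  lam_grid <- vapply(t0_grid, function(t0)
    decay_rate_from_t0(t0, 0.7)$lambda, numeric(1))
  expect_true(all(diff(lam_grid) < 0))
})
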