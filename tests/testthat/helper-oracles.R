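# independent numeric oracles used across test files

# central finite-difference hazard: -d ln S / dt
fd_hazard <- function(surv_fn, t, h = 1e-5) {
  (log(surv_fn(t - h)) - log(surv_fn(t + h))) / (2 * h)
}

# cumulative hazard by adaptive quadrature
quad_cumhaz <- function(hazard_fn, t, rel.tol = 1e-10) {
  stats::integrate(hazard_fn, 0, t, rel.tol = rel.tol)$value
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# exact hazard of the mechanistic network (series of m modules, each with a
# conditioned-binomial number of parallel exponential interactions),
# independent of the package's closed forms
exact_mech_hazard <- function(spec, t, h = 1e-4) {
  kp <- stats::dbinom(seq_len(spec$n), spec$n, spec$p)
  kp <- kp / sum(kp)
  s_mod <- function(tt) vapply(tt, function(x)
    sum(kp * (1 - (-expm1(-spec$lambda * x))^seq_len(spec$n))), numeric(1))
  spec$m * (log(s_mod(t - h)) - log(s_mod(t + h))) / (2 * h)
}

by4742 <- function() network_params(R = 0.0047, t0 = 56.2, n = 7.9)
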