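# Shared fixtures: all built in code, dimensionless units (sigma_0 = K_w = 1).

default_wall <- function(eta_w = 1, Y = 1, K_w = 1) {
  wall_params(K_w = K_w, eta_w = eta_w, Y = Y)
}

default_minor <- function(tau_s = 1, K_s = 1) {
  minor_sensor_params(K_s = K_s, eta_s = tau_s * K_s)
}

default_seg <- function(wall = default_wall(), k_s = 0.01, l = 1) {
  segment_bond_params(k_s = k_s, l = l, wall = wall)
}

default_law <- function(tau_c = 1, F_c = Inf, beta = 5) {
  dissociation_law(tau_c = tau_c, F_c = F_c, beta = beta)
}

constant_signal <- function(value, kind, t1 = 10, n = 1000, ...) {
  g <- make_grid(0, t1, n)
  ws_signal(g$time, rep(value, n + 1), kind, ...)
}

# direct-quadrature oracle for the minor branch: K_s int e^{-(t-t')/tau_s}
# rate(t') dt' via trapezoidal quadrature of e^{t'/tau} r(t'), an
# integration route independent of the exponential-integrator path
minor_quadrature_oracle <- function(strain_rate, sensor) {
  t <- strain_rate$time
  r <- strain_rate$value
  g <- exp((t - t[length(t)]) / sensor$tau_s) * r # shifted to avoid overflow
  cum <- c(0, cumsum(diff(t) * (g[-length(g)] + g[-1]) / 2))
  sensor$K_s * exp((t[length(t)] - t) / sensor$tau_s) * cum
}

# stationary renewal oracle under constant loading rate: fine-quadrature
# detach-age density h(a) S(a) for F(a) = ksl * rate * a
stationary_oracle <- function(rate, seg, law, da = 1e-4, a_max = 40) {
  a <- seq(0, a_max * law$tau_c, by = da * law$tau_c)
  h <- hazard(seg$ksl * rate * a, law)
  H <- c(0, cumsum(diff(a) * (h[-length(h)] + h[-1]) / 2))
  S <- exp(-H)
  w <- S * h
  list(
    D = sum(w * seg$ksl * rate * a) / sum(w),
    R = sum(w) / sum(S)
  )
}

expect_signal_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$time, b$time, tolerance = tol)
  expect_equal(a$value, b$value, tolerance = tol)
  expect_identical(signal_kind(a), signal_kind(b))
}
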