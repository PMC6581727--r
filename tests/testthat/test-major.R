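test_that("segment-bond and dissociation-law invariants are enforced", {
  wall <- default_wall(eta_w = 2)
  seg <- segment_bond_params(0.01, 0.5, wall = wall)
  expect_equal(seg$k_w, 1 / 0.5)
  expect_equal(seg$alpha_w, 2 / 0.5)
  expect_equal(seg$ksl, 0.005)
  expect_warning(segment_bond_params(0.5, 1, wall = wall),
    class = "wallsense_soft_sensor"
  )
  expect_error(segment_bond_params(0.01, 1), class = "wallsense_bad_params")
  expect_error(dissociation_law(1, 1, f = function(x) 2 * exp(x)),
    class = "wallsense_bad_params"
  ) # f(0) != 1
  expect_error(dissociation_law(1, 1, f = function(x) exp(-x) * (1 + x) / (1 + x)^3),
    class = "wallsense_bad_params"
  ) # decreasing
  expect_error(dissociation_law(-1, 1), "tau_c")
})

test_that("bond force follows the wall stretch from the binding strain", {
  seg <- default_seg()
  g <- make_grid(0, 10, 1000)
  # constant strain: no stretching, no force
  flat <- ws_signal(g$time, rep(0.2, 1001), "strain")
  expect_true(all(bound_force(flat, 3, seg)$value == 0))
  # linear loading k_s l r (t - t_b), zero before and at binding
  ramp <- ws_signal(g$time, 0.5 * g$time, "strain")
  f <- bound_force(ramp, 4, seg)
  expect_equal(f$value[g$time < 4], rep(0, sum(g$time < 4)))
  expect_equal(
    f$value[g$time >= 4],
    seg$ksl * 0.5 * (g$time[g$time >= 4] - 4),
    tolerance = 1e-12
  )
  expect_error(bound_force(ramp, 11, seg), class = "wallsense_bad_params")
})

test_that("hazard is the Bell amplification of the zero-force rate", {
  law <- dissociation_law(tau_c = 2, F_c = 0.1, beta = 5)
  expect_equal(hazard(0, law), 1 / 2)
  expect_equal(hazard(0.1, law), exp(5) / 2)
  expect_equal(hazard(-0.1, law), exp(5) / 2) # magnitude of the deformation
  # high dissociation force limit: rate pinned at 1/tau_c
  inf_law <- dissociation_law(tau_c = 2, F_c = Inf)
  expect_equal(hazard(c(0, 1, 100), inf_law), rep(1 / 2, 3))
})

test_that("survival is exponential at zero force and always a survival curve", {
  seg <- default_seg()
  law <- default_law(tau_c = 0.8)
  g <- make_grid(0, 10, 2000)
  flat <- ws_signal(g$time, rep(0, 2001), "strain")
  S <- survival(flat, 1, seg, law)
  ref <- ifelse(g$time <= 1, 1, exp(-(g$time - 1) / 0.8))
  expect_lt(max(abs(S$value - ref)), 1e-8)
  expect_equal(S$value[g$time == 1], 1)
  # property: monotone non-increasing in [0, 1] for arbitrary loading
  set.seed(7)
  for (k in 1:4) {
    eps <- cumulative_integral(
      ws_signal(g$time, abs(stats::rnorm(2001, sd = 0.3)), "strain_rate")
    )
    law2 <- dissociation_law(1, 0.01, beta = 3)
    Sk <- survival(eps, 2, default_seg(), law2)
    expect_true(all(Sk$value >= 0 & Sk$value <= 1))
    expect_true(all(diff(Sk$value) <= 1e-15))
  }
})

test_that("an unloaded population detaches at the floor rate with zero force", {
  wall <- default_wall()
  seg <- default_seg(wall)
  law <- dissociation_law(1, 0.005, beta = 3)
  g <- make_grid(0, 10, 1000)
  input <- ws_signal(g$time, rep(0, 1001), "strain_rate")
  pop <- population_response(input, wall, seg, law)
  expect_true(all(pop$detach_force == 0))
  expect_equal(pop$rate, rep(1, nrow(pop)), tolerance = 1e-12)
  expect_equal(pop$attached, rep(1, nrow(pop)), tolerance = 1e-12)
})

test_that("constant growth at infinite F_c yields mean force k_s l r tau_c", {
  wall <- default_wall()
  seg <- default_seg(wall)
  law <- default_law(tau_c = 1, F_c = Inf)
  g <- make_grid(0, 20, 4000)
  r <- 1
  input <- ws_signal(g$time, rep(r, 4001), "strain_rate", reference_scale = 1)
  pop <- population_response(input, wall, seg, law)
  iw <- pop$time >= 10
  expect_equal(mean(pop$detach_force[iw]), seg$ksl * r * law$tau_c,
    tolerance = 0.01
  )
  # caption normalization: steady normalized output = steady normalized input
  expect_equal(mean(pop$detach_force_norm[iw]), 1, tolerance = 0.01)
})

test_that("renewal steady state matches the stationary-age quadrature oracle", {
  wall <- default_wall(eta_w = 0.1)
  seg <- default_seg(wall)
  law <- dissociation_law(1, 0.05, beta = 3)
  g <- make_grid(0, 10, 2000)
  input <- ws_signal(g$time, rep(2, 2001), "stress", offset = 1)
  pop <- population_response(input, wall, seg, law)
  oracle <- stationary_oracle(rate = 10, seg, law, da = 1e-5, a_max = 3)
  iw <- pop$time >= 5
  expect_equal(mean(pop$rate[iw]), oracle$R, tolerance = 0.01)
  expect_equal(mean(pop$detach_force[iw]), oracle$D, tolerance = 0.01)
})

test_that("immediate rebinding conserves the sensor population exactly", {
  tr <- run_scenario("fig5D")
  expect_lt(max(abs(tr$attached - 1)), 1e-9)
  expect_true(all(tr$rate_norm >= 1 - 1e-12)) # hazard floor 1/tau_c
})

test_that("ensembles are reproducible and demand a seed", {
  wall <- default_wall()
  seg <- default_seg(wall)
  law <- default_law()
  g <- make_grid(0, 5, 500)
  input <- ws_signal(g$time, rep(1, 501), "strain_rate")
  expect_error(simulate_ensemble(input, wall, seg, law, 10),
    class = "wallsense_need_seed"
  )
  e1 <- simulate_ensemble(input, wall, seg, law, 200, seed = 11)
  e2 <- simulate_ensemble(input, wall, seg, law, 200, seed = 11)
  expect_identical(e1$events, e2$events)
  e3 <- simulate_ensemble(input, wall, seg, law, 200, seed = 12)
  expect_false(identical(e1$events, e3$events))
})

test_that("unloaded bonds live tau_c on average in the stochastic ensemble", {
  wall <- default_wall()
  seg <- default_seg(wall)
  law <- default_law(tau_c = 1, F_c = Inf)
  g <- make_grid(0, 12, 1200)
  input <- ws_signal(g$time, rep(0, 1201), "strain_rate")
  n <- 3000
  ens <- simulate_ensemble(input, wall, seg, law, n, seed = 5)
  # per-sensor event rate over the window estimates 1/tau_c
  rate_hat <- nrow(ens$events) / (n * 12)
  se <- sqrt(nrow(ens$events)) / (n * 12)
  expect_lt(abs(rate_hat - 1), 3 * se)
  expect_true(all(ens$events$force == 0))
})

test_that("ensemble mean detachment force matches the renewal prediction", {
  wall <- default_wall()
  seg <- default_seg(wall)
  law <- default_law(tau_c = 1, F_c = Inf)
  g <- make_grid(0, 20, 2000)
  input <- ws_signal(g$time, rep(1, 2001), "strain_rate")
  ens <- simulate_ensemble(input, wall, seg, law, 3000, seed = 9)
  ev <- ens$events[ens$events$time >= 8, ]
  se <- stats::sd(ev$force) / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$force) - seg$ksl * 1 * law$tau_c), 3 * se)
})

test_that("regime classification follows lifetime, force scale, and yield", {
  wall <- default_wall(eta_w = 1, Y = 1)
  seg <- default_seg(wall)
  base <- list(sigma_background = 2)
  expect_equal(
    classify_regime(wall, seg, dissociation_law(1, Inf), base),
    "long_lived_high_Fc"
  )
  expect_equal(
    classify_regime(
      default_wall(eta_w = 5), seg, dissociation_law(1, Inf), base
    ),
    "short_lived_high_Fc"
  )
  low <- dissociation_law(1, 0.5 * seg$k_s / seg$k_w * 1)
  expect_equal(
    classify_regime(default_wall(Y = 3), seg, low, list(sigma_background = 1)),
    "low_Fc_elastic"
  )
  expect_equal(classify_regime(wall, seg, low, base), "low_Fc_viscous")
  expect_error(classify_regime(wall, seg, low, list()),
    class = "wallsense_bad_params"
  )
})

test_that("strain-driven responses ignore wall viscosity and yield", {
  seg_args <- list(k_s = 0.01, l = 1)
  law <- dissociation_law(1, 0.005, beta = 3)
  g <- make_grid(0, 10, 1000)
  input <- constant_plus_pulse(pulse_spec(1, 1, 5, 1), g, "strain_rate")
  runs <- lapply(
    list(default_wall(eta_w = 1, Y = 1), default_wall(eta_w = 7, Y = 0.2)),
    function(w) {
      seg <- segment_bond_params(seg_args$k_s, seg_args$l, wall = w)
      population_response(input, w, seg, law)
    }
  )
  expect_lt(max(abs(runs[[1]]$detach_force - runs[[2]]$detach_force)), 1e-10)
  expect_lt(max(abs(runs[[1]]$rate - runs[[2]]$rate)), 1e-10)
})

test_that("regime sweep tabulates all four regimes", {
  tab <- regime_sweep()
  expect_equal(nrow(tab), 9)
  expect_setequal(
    unique(tab$regime),
    c(
      "long_lived_high_Fc", "short_lived_high_Fc",
      "low_Fc_elastic", "low_Fc_viscous"
    )[c(1, 2, 4)] # background above yield here: elastic never appears
  )
})
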