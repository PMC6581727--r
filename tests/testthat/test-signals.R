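test_that("make_grid builds uniform grids and rejects bad spans", {
  g <- make_grid(0, 10, 10)
  expect_equal(g$dt, 1)
  expect_equal(g$time, 0:10)
  expect_equal(make_grid(0, 30, 3000)$dt, 0.01)
  expect_error(make_grid(0, 10, 1), class = "wallsense_bad_grid")
  expect_error(make_grid(5, 5, 10), class = "wallsense_bad_grid")
  expect_error(make_grid(3, 1, 10), class = "wallsense_bad_grid")
})

test_that("check_resolution warns or errors on coarse grids", {
  g <- make_grid(0, 10, 100) # dt = 0.1
  expect_warning(check_resolution(g, 1), class = "wallsense_coarse_grid")
  expect_error(
    check_resolution(g, 1, on_coarse = "error"),
    class = "wallsense_coarse_grid"
  )
  expect_silent(check_resolution(g, 10))
})

test_that("background-plus-pulse waveforms honour the FWHM parameterization", {
  g <- make_grid(0, 20, 4000)
  for (shape in c("gaussian", "raised_cosine")) {
    spec <- pulse_spec(1, 1, 10, 2, shape = shape)
    sig <- constant_plus_pulse(spec, g, "stress")
    at <- function(t) approx(sig$time, sig$value, xout = t)$y
    expect_equal(at(10), 2, tolerance = 1e-12) # baseline + amplitude
    # width is full width at half maximum for both shapes
    expect_equal(at(10 - 1), 1.5, tolerance = 1e-9)
    expect_equal(at(10 + 1), 1.5, tolerance = 1e-9)
    # symmetric about the center
    expect_equal(at(10 + 0.7), at(10 - 0.7), tolerance = 1e-9)
  }
  # degenerate pulse: amplitude 0 is a constant signal
  flat <- constant_plus_pulse(pulse_spec(3, 0, 10, 2), g, "stress")
  expect_true(all(flat$value == 3))
  # gaussian far field; raised cosine is exactly compact
  gau <- constant_plus_pulse(pulse_spec(0, 1, 10, 1), g, "stress")
  expect_lt(max(abs(gau$value[abs(gau$time - 10) > 3])), 1e-3)
  rc <- constant_plus_pulse(
    pulse_spec(0, 1, 10, 1, shape = "raised_cosine"), g, "stress"
  )
  expect_true(all(rc$value[abs(rc$time - 10) >= 1] == 0))
  expect_error(pulse_spec(1, 1, 10, 0), class = "wallsense_bad_pulse")
})

test_that("normalization subtracts the offset, scales, and round-trips", {
  Y <- 2
  sigma0 <- 0.5
  sig <- constant_signal(Y, "stress", reference_scale = sigma0, offset = Y)
  expect_true(all(normalize(sig)$value == 0))
  sig2 <- constant_signal(Y + sigma0, "stress",
    reference_scale = sigma0, offset = Y
  )
  expect_true(all(normalize(sig2)$value == 1))
  # force normalized by F_0 = K_s/K_w sigma_0
  F0 <- 1 / 1 * sigma0
  f <- constant_signal(F0, "force", reference_scale = F0)
  expect_true(all(normalize(f)$value == 1))
  # round trip is the identity for arbitrary signals
  set.seed(1)
  for (k in 1:5) {
    g <- make_grid(0, 5, 100)
    raw <- ws_signal(g$time, stats::rnorm(101, sd = 3), "strain_rate",
      reference_scale = stats::runif(1, 0.1, 10),
      offset = stats::rnorm(1)
    )
    back <- denormalize(normalize(raw))
    expect_equal(back$value, raw$value, tolerance = 1e-12)
  }
  expect_error(
    ws_signal(1:3, 1:3, "stress", reference_scale = -1),
    class = "wallsense_bad_signal"
  )
})

test_that("numerical derivative is exact on polynomials of degree one", {
  g <- make_grid(0, 10, 100)
  const <- ws_signal(g$time, rep(4, 101), "stress")
  expect_true(all(numerical_derivative(const)$value == 0))
  ramp <- ws_signal(g$time, 2.5 * g$time, "strain")
  d <- numerical_derivative(ramp)
  expect_equal(d$value, rep(2.5, 101), tolerance = 1e-12)
  expect_identical(signal_kind(d), "strain_rate")
  expect_error(
    numerical_derivative(ws_signal(c(0, 1), c(0, 1), "stress")),
    class = "wallsense_bad_signal"
  )
})

test_that("numerical derivative of a gaussian converges at second order", {
  err <- vapply(c(500, 1000), function(n) {
    g <- make_grid(0, 20, n)
    spec <- pulse_spec(0, 1, 10, 2)
    sig <- constant_plus_pulse(spec, g, "stress")
    d <- numerical_derivative(sig)
    exact <- -8 * log(2) * (g$time - 10) / 4 *
      exp(-4 * log(2) * ((g$time - 10) / 2)^2)
    max(abs(d$value - exact))
  }, numeric(1))
  expect_lt(err[2], err[1] / 3) # O(dt^2): halving dt cuts error ~4x
  # antisymmetric about the center, zero at the center
  g <- make_grid(0, 20, 1000)
  d <- numerical_derivative(constant_plus_pulse(
    pulse_spec(0, 1, 10, 2), g, "stress"
  ))
  i <- which(g$time == 10)
  expect_equal(d$value[i], 0, tolerance = 1e-10)
  expect_equal(d$value[i + 50], -d$value[i - 50], tolerance = 1e-10)
})

test_that("derivative and integral are linear operators", {
  g <- make_grid(0, 5, 200)
  f1 <- ws_signal(g$time, sin(g$time), "strain")
  f2 <- ws_signal(g$time, g$time^2, "strain")
  lhs <- numerical_derivative(
    ws_signal(g$time, 2 * f1$value - 3 * f2$value, "strain")
  )
  rhs <- 2 * numerical_derivative(f1)$value - 3 * numerical_derivative(f2)$value
  expect_equal(lhs$value, rhs, tolerance = 1e-12)
})

test_that("cumulative integral inverts differentiation of smooth signals", {
  g <- make_grid(0, 10, 2000)
  r <- ws_signal(g$time, cos(g$time), "strain_rate")
  eps <- cumulative_integral(r, init = 0)
  expect_identical(signal_kind(eps), "strain")
  expect_equal(eps$value, sin(g$time), tolerance = 1e-5)
})

test_that("signal CSV serialization round-trips exactly", {
  g <- make_grid(0, 3, 50)
  sig <- ws_signal(g$time, exp(sin(g$time)), "strain_rate",
    reference_scale = pi, offset = 0.1, units = "1/s"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, path)
  back <- read_signal_csv(path)
  expect_signal_equal(back, sig, tol = 1e-15)
  expect_equal(reference_scale(back), pi)
  expect_equal(signal_offset(back), 0.1)
})
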