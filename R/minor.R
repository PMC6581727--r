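#' Minor load-bearing sensor-branch parameters
#'
#' A sensor associated with a minor load-bearing structure (a matrix
#' component or the plasma membrane) is a spring of stiffness `K_s` (sensor
#' plus structure combined) in series with a dashpot of viscosity `eta_s`
#' (the structure's remodeling/turnover), the branch lying in parallel with
#' the bulk wall and carrying negligible load. The branch relaxation time is
#' `tau_s = eta_s / K_s`; because the wall relaxes no faster than any of its
#' constituents, `tau_s` should not exceed `tau_w` (a warning is emitted when
#' a pairing violates this).
#'
#' @param K_s Branch elastic modulus (stress units), > 0.
#' @param eta_s Branch viscosity (stress x time), > 0.
#' @param F_init Initial branch force; the character value `"steady"`
#'   (default) asks solvers to start from the steady state of the background
#'   input.
#' @return A `ws_minor_sensor` list with derived `tau_s`.
#' @export
minor_sensor_params <- function(K_s, eta_s, F_init = "steady") {
  stopifnot(is.numeric(K_s), is.numeric(eta_s))
  if (K_s <= 0 || eta_s <= 0) {
    abort("Need K_s > 0 and eta_s > 0.", class = "wallsense_bad_params")
  }
  if (!(identical(F_init, "steady") ||
    (is.numeric(F_init) && length(F_init) == 1 && is.finite(F_init)))) {
    abort("`F_init` must be a number or \"steady\".",
      class = "wallsense_bad_params"
    )
  }
  structure(
    list(K_s = K_s, eta_s = eta_s, tau_s = eta_s / K_s, F_init = F_init),
    class = "ws_minor_sensor"
  )
}

#' @export
print.ws_minor_sensor <- function(x, ...) {
  cat(sprintf(
    "<ws_minor_sensor> K_s = %g, eta_s = %g (tau_s = %g)\n",
    x$K_s, x$eta_s, x$tau_s
  ))
  invisible(x)
}

check_tau_order <- function(sensor, wall) {
  if (sensor$tau_s > wall$tau_w * (1 + 1e-12)) {
    warn(
      sprintf(
        "tau_s = %g exceeds tau_w = %g; the wall cannot relax faster than its constituents.",
        sensor$tau_s, wall$tau_w
      ),
      class = "wallsense_tau_order"
    )
  }
  invisible(NULL)
}

#' Sensor force driven by an imposed strain-rate history
#'
#' The branch ODE is `dF/dt = K_s * eps_dot(t) - F / tau_s`: the force is
#' `K_s` times the exponential moving average of the strain rate over
#' `tau_s`. Each step uses the exact exponential integrator
#' `F[i+1] = F[i] e^{-dt/tau_s} + K_s tau_s (1 - e^{-dt/tau_s}) *
#' (eps_dot[i] + eps_dot[i+1]) / 2`, which is exact for constant input and
#' second-order accurate otherwise.
#'
#' @param strain_rate A `ws_signal` of kind `"strain_rate"`.
#' @param sensor A [minor_sensor_params()] object.
#' @param F_init Initial force; defaults to the sensor's `F_init` field
#'   (`"steady"` means the fixed point `K_s * tau_s * eps_dot(t0)`).
#' @return A `ws_signal` of kind `"force"` on the same grid.
#' @export
force_from_strain_rate <- function(strain_rate, sensor, F_init = NULL) {
  check_kind(strain_rate, "strain_rate", "strain_rate")
  stopifnot(inherits(sensor, "ws_minor_sensor"))
  grid <- signal_grid(strain_rate)
  check_resolution(grid, sensor$tau_s, "tau_s")
  if (is.null(F_init)) F_init <- sensor$F_init
  r <- strain_rate$value
  if (identical(F_init, "steady")) F_init <- sensor$K_s * sensor$tau_s * r[1]
  dt <- grid$dt
  n <- length(r)
  decay <- exp(-dt / sensor$tau_s)
  gain <- sensor$K_s * sensor$tau_s * (1 - decay)
  mid <- (r[-n] + r[-1]) / 2
  f <- numeric(n)
  f[1] <- F_init
  for (i in seq_len(n - 1)) {
    f[i + 1] <- f[i] * decay + gain * mid[i]
  }
  ws_signal(strain_rate$time, f, kind = "force", units = "force")
}

#' Minor-sensor response to an imposed stress history
#'
#' Composes the wall law ([strain_rate_from_stress()]) with the branch ODE
#' ([force_from_strain_rate()]): parallel branches share the strain, so the
#' branch is strain-driven by the wall. Returns a response trace with the
#' normalized input `(sigma - Y)/sigma_0` and normalized output `F / F_0`,
#' `F_0 = (K_s / K_w) sigma_0`.
#'
#' @param stress A `ws_signal` of kind `"stress"`; its `reference_scale` is
#'   `sigma_0` and its `offset` (typically `Y`, or 0 for a non-growing wall)
#'   is used for the normalized input.
#' @param wall A [wall_params()] object.
#' @param sensor A [minor_sensor_params()] object.
#' @param F_init Optional override of the initial force.
#' @return A `ws_response` tibble with columns `time`, `input`, `output`
#'   (both normalized) and `force` (raw), carrying the normalization
#'   constants as attributes.
#' @export
force_from_stress <- function(stress, wall, sensor, F_init = NULL) {
  check_kind(stress, "stress", "stress")
  stopifnot(inherits(wall, "ws_wall"), inherits(sensor, "ws_minor_sensor"))
  check_tau_order(sensor, wall)
  rate <- strain_rate_from_stress(stress, wall)
  force <- force_from_strain_rate(rate, sensor, F_init = F_init)
  sigma0 <- reference_scale(stress)
  F0 <- sensor$K_s / wall$K_w * sigma0
  input_norm <- (stress$value - signal_offset(stress)) / sigma0
  new_response(
    time = stress$time,
    input = input_norm,
    output = force$value / F0,
    extra = list(force = force$value),
    trace_kind = "minor_force",
    normalization = list(
      sigma_0 = sigma0, Y = wall$Y, offset = signal_offset(stress),
      F_0 = F0, tau_ref = sensor$tau_s
    ),
    params = list(wall = wall, sensor = sensor)
  )
}

#' Steady-state force of the minor sensor (analytic oracle)
#'
#' Fixed points of the branch dynamics under constant input: for a constant
#' strain rate `r`, `F = K_s * tau_s * r`; for a constant stress `sigma`
#' applied to the wall, `F = (K_s/K_w) (tau_s/tau_w) max(sigma - Y, 0)` (zero
#' below yield, where the wall does not flow and the branch fully relaxes).
#'
#' @param input Constant input value (stress or strain rate).
#' @param sensor A [minor_sensor_params()] object.
#' @param wall A [wall_params()] object; required for stress input, ignored
#'   for strain-rate input.
#' @param kind `"stress"` or `"strain_rate"`.
#' @return The steady force (a number).
#' @export
steady_state_force <- function(input, sensor, wall = NULL,
                               kind = c("stress", "strain_rate")) {
  kind <- arg_match(kind)
  stopifnot(inherits(sensor, "ws_minor_sensor"))
  if (kind == "strain_rate") {
    return(sensor$K_s * sensor$tau_s * input)
  }
  if (is.null(wall)) {
    abort("Stress input needs `wall`.", class = "wallsense_bad_params")
  }
  sensor$K_s / wall$K_w * (sensor$tau_s / wall$tau_w) * max(input - wall$Y, 0)
}

# Shared constructor for normalized input/output response traces.
new_response <- function(time, input, output, extra = list(), trace_kind,
                         normalization, params = list()) {
  cols <- c(
    list(time = as.double(time), input = as.double(input),
         output = as.double(output)),
    extra
  )
  out <- new_tibble(cols, nrow = length(time), class = "ws_response")
  attr(out, "trace_kind") <- trace_kind
  attr(out, "normalization") <- normalization
  attr(out, "params") <- params
  out
}

#' @export
print.ws_response <- function(x, ...) {
  cat(sprintf(
    "<ws_response> %s, %d points (normalized input/output)\n",
    attr(x, "trace_kind"), nrow(x)
  ))
  NextMethod()
}
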