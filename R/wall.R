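#' Viscoelastoplastic cell-wall parameters
#'
#' The wall is a spring (elastic modulus `K_w`) and a dashpot (viscosity
#' `eta_w`) in series with a frictional yield block: below the yield threshold
#' `Y` the wall is purely elastic; above it the block slides and the wall
#' flows irreversibly, as in Lockhart/Ortega growth models. The derived
#' relaxation time is `tau_w = eta_w / K_w`.
#'
#' @param K_w Elastic modulus (stress units), > 0.
#' @param eta_w Viscosity (stress x time), > 0.
#' @param Y Yield threshold (stress units), >= 0.
#' @return A `ws_wall` list with fields `K_w`, `eta_w`, `Y` and derived
#'   `tau_w`.
#' @export
wall_params <- function(K_w, eta_w, Y) {
  stopifnot(is.numeric(K_w), is.numeric(eta_w), is.numeric(Y))
  if (K_w <= 0 || eta_w <= 0 || Y < 0) {
    abort("Need K_w > 0, eta_w > 0, Y >= 0.", class = "wallsense_bad_params")
  }
  structure(
    list(K_w = K_w, eta_w = eta_w, Y = Y, tau_w = eta_w / K_w),
    class = "ws_wall"
  )
}

#' @export
print.ws_wall <- function(x, ...) {
  cat(sprintf(
    "<ws_wall> K_w = %g, eta_w = %g, Y = %g (tau_w = %g)\n",
    x$K_w, x$eta_w, x$Y, x$tau_w
  ))
  invisible(x)
}

#' Wall strain rate under an imposed stress history
#'
#' The constitutive law: `eps_dot(t) = sigma_dot(t)/K_w +
#' max(sigma(t) - Y, 0)/eta_w`. The elastic term uses
#' [numerical_derivative()]; the plastic term engages only above yield
#' (sharp threshold, no smoothing). A stress step is resolved by the discrete
#' derivative as a jump spread over one grid step.
#'
#' @param stress A `ws_signal` of kind `"stress"`.
#' @param wall A [wall_params()] object.
#' @return A `ws_signal` of kind `"strain_rate"` on the same grid, with
#'   reference scale `sigma_0 / (K_w * tau_w)` where `sigma_0` is the stress
#'   signal's reference scale.
#' @export
strain_rate_from_stress <- function(stress, wall) {
  check_kind(stress, "stress", "stress")
  stopifnot(inherits(wall, "ws_wall"))
  # the law is algebraic in (sigma, sigma_dot); accuracy is set by how well
  # the grid resolves the stress waveform, not by tau_w
  sdot <- numerical_derivative(stress)
  rate <- sdot$value / wall$K_w + pmax(stress$value - wall$Y, 0) / wall$eta_w
  ws_signal(stress$time, rate,
    kind = "strain_rate",
    reference_scale = reference_scale(stress) / (wall$K_w * wall$tau_w),
    units = "per time"
  )
}

#' Wall strain under an imposed stress history
#'
#' Trapezoidal time integral of [strain_rate_from_stress()], starting at
#' `eps0`.
#'
#' @inheritParams strain_rate_from_stress
#' @param eps0 Strain at the first grid point.
#' @return A `ws_signal` of kind `"strain"`.
#' @export
strain_from_stress <- function(stress, wall, eps0 = 0) {
  rate <- strain_rate_from_stress(stress, wall)
  cumulative_integral(rate, init = eps0, kind = "strain")
}

#' Stress relaxation at fixed strain (analytic oracle)
#'
#' Under constant strain with the yield block engaged, wall stress relaxes
#' exponentially to zero with time constant `tau_w`:
#' `sigma(t) = sigma_init * exp(-t / tau_w)`. This closed form is the module's
#' test oracle; it is not used in simulation pipelines. Below yield the block
#' does not slide and the wall is treated as purely elastic (no relaxation),
#' so `sigma_init` should exceed `Y` for the formula to describe the model.
#'
#' @param wall A [wall_params()] object.
#' @param sigma_init Initial stress.
#' @param grid A [make_grid()] grid; relaxation time is measured from
#'   `grid$t0`.
#' @return A `ws_signal` of kind `"stress"`.
#' @export
stress_relaxation_fixed_strain <- function(wall, sigma_init, grid) {
  stopifnot(inherits(wall, "ws_wall"), inherits(grid, "ws_grid"))
  value <- sigma_init * exp(-(grid$time - grid$t0) / wall$tau_w)
  signal_from_grid(grid, value, "stress")
}
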