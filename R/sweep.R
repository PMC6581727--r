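#' Regime table over sensor kinetic parameters
#'
#' Classifies the major-sensor regime ([classify_regime()]) on a grid of
#' lifetime ratios `tau_c / tau_w` and dissociation-force scales `F_c`
#' (expressed in units of `F_0 = (k_s / k_w) sigma_background`), at a fixed
#' wall and background stress.
#'
#' @param tau_c_over_tau_w Numeric vector of lifetime ratios.
#' @param F_c_over_F0 Numeric vector of force-scale ratios (may include
#'   `Inf`).
#' @param sigma_background Background stress level.
#' @param wall A [wall_params()]; defaults to `K_w = 1, eta_w = 1, Y = 1`.
#' @param seg A [segment_bond_params()]; defaults to `k_s = 0.01, l = 1`
#'   derived from `wall`.
#' @return A tibble with one row per combination and its regime label.
#' @export
regime_sweep <- function(tau_c_over_tau_w = c(0.2, 1, 5),
                         F_c_over_F0 = c(0.5, 20, Inf),
                         sigma_background = 2,
                         wall = wall_params(1, 1, 1),
                         seg = segment_bond_params(0.01, 1, wall = wall)) {
  grid <- tidyr::expand_grid(
    tau_c_over_tau_w = tau_c_over_tau_w,
    F_c_over_F0 = F_c_over_F0
  )
  F0 <- seg$k_s / seg$k_w * sigma_background
  grid |>
    mutate(
      regime = purrr::map2_chr(
        .data$tau_c_over_tau_w, .data$F_c_over_F0,
        function(tr, fr) {
          law <- dissociation_law(tau_c = tr * wall$tau_w, F_c = fr * F0)
          classify_regime(wall, seg, law,
            input_summary = list(sigma_background = sigma_background)
          )
        }
      )
    )
}
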