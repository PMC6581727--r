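# The qualitative response signatures of the sensing regimes, made
# machine-checkable. Each check runs a preset end-to-end, summarizes the
# trace, and reports a pass flag plus the margin by which the decisive
# feature clears the detection threshold (prominence margin, ratio margin,
# or monotonicity slack).

signature_one <- function(name, pass, margin, detail) {
  tibble(
    check = name, pass = isTRUE(pass), margin = margin, detail = detail
  )
}

#' Run the response-signature suite
#'
#' Checks the qualitative signatures of all sensing regimes on their presets:
#' long-lived high-F_c (stress pulse gives one detachment-force peak followed
#' by one dip below the pre-pulse baseline), short-lived high-F_c (two
#' consecutive peaks), low-F_c elastic wall (two dissociation-rate peaks with
#' the largest output jump at the stress-derivative sign change), low-F_c
#' viscous wall (a single rate peak), the attenuation of the fast-relaxing
#' minor branch relative to the matched branch, and the monotone widening of
#' the strain-rate pulse response with the sensor's integration time
#' (`tau_s` for the minor sensor, `tau_c` for the major sensor).
#'
#' @param prominence Prominence threshold for peak/dip detection (fraction of
#'   output range).
#' @return A tibble with one row per check: `check`, `pass`, `margin`
#'   (how many times the decisive quantity clears its threshold) and
#'   `detail`.
#' @export
run_signature_checks <- function(prominence = 0.02) {
  out <- list()

  # long-lived, high F_c: one peak then one dip below the pre-pulse level
  tr <- run_scenario("fig5C")
  s <- summarize_trace(tr, prominence)
  peak_ok <- s$n_peaks == 1 && s$n_dips == 1 &&
    s$peak_times[[1]][1] < s$dip_times[[1]][1] &&
    s$dip_values[[1]][1] < s$steady_pre
  margin <- min(
    s$peak_prominences[[1]], s$dip_prominences[[1]]
  ) / (prominence * s$output_range)
  out$fig5C <- signature_one(
    "long_lived_high_Fc_peak_then_dip", peak_ok, margin,
    sprintf("%d peak(s), %d dip(s)", s$n_peaks, s$n_dips)
  )

  # short-lived, high F_c: two consecutive peaks in the detachment force
  tr <- run_scenario("fig5D")
  s <- summarize_trace(tr, prominence)
  margin <- if (s$n_peaks >= 2) {
    sort(s$peak_prominences[[1]], decreasing = TRUE)[2] /
      (prominence * s$output_range)
  } else {
    0
  }
  out$fig5D <- signature_one(
    "short_lived_high_Fc_two_peaks", s$n_peaks == 2, margin,
    sprintf("%d peak(s)", s$n_peaks)
  )

  # low F_c, elastic wall: two rate peaks, largest jump at the stress
  # derivative sign change (the pulse maximum)
  sc <- load_scenario("fig5G")
  tr <- run_scenario(sc)
  s <- summarize_trace(tr, prominence)
  at_center <- abs(s$discontinuity_time - sc$pulse$center) <= sc$pulse$width
  margin <- if (s$n_peaks >= 2) {
    sort(s$peak_prominences[[1]], decreasing = TRUE)[2] /
      (prominence * s$output_range)
  } else {
    0
  }
  out$fig5G <- signature_one(
    "low_Fc_elastic_two_peaks_discontinuity",
    s$n_peaks == 2 && s$max_abs_discontinuity > 0 && at_center, margin,
    sprintf(
      "%d peak(s); max jump %.3g at t = %.2f (pulse center %.2f)",
      s$n_peaks, s$max_abs_discontinuity, s$discontinuity_time,
      sc$pulse$center
    )
  )

  # low F_c, viscous wall: a single rate peak
  tr <- run_scenario("fig5F")
  s <- summarize_trace(tr, prominence)
  margin <- if (s$n_peaks >= 1) {
    max(s$peak_prominences[[1]]) / (prominence * s$output_range)
  } else {
    0
  }
  out$fig5F <- signature_one(
    "low_Fc_viscous_single_peak", s$n_peaks == 1, margin,
    sprintf("%d peak(s)", s$n_peaks)
  )

  # fast-relaxing minor branch: steady output attenuated below 0.25x the
  # matched-branch case
  s4C <- summarize_trace(run_scenario("fig4C"), prominence)
  s4D <- summarize_trace(run_scenario("fig4D"), prominence)
  base_ratio <- max(abs(s4C$steady_pre), abs(s4C$steady_post)) /
    max(abs(s4D$steady_pre), abs(s4D$steady_post))
  out$fig4C <- signature_one(
    "minor_fast_branch_attenuation", base_ratio < 0.25, 0.25 / base_ratio,
    sprintf("steady-output ratio fig4C/fig4D = %.3g", base_ratio)
  )

  # smoothing: strain-rate pulse response widens with the integration time
  widths_minor <- smoothing_widths_minor()
  widths_major <- smoothing_widths_major()
  mono <- function(w) all(diff(w) > 0)
  out$smoothing <- signature_one(
    "strain_rate_pulse_smoothing_monotone",
    mono(widths_minor) && mono(widths_major),
    min(
      min(diff(widths_minor) / widths_minor[-length(widths_minor)]),
      min(diff(widths_major) / widths_major[-length(widths_major)])
    ), # smallest relative widening across consecutive integration times
    sprintf(
      "minor FWHM: %s; major FWHM: %s",
      paste(sprintf("%.3f", widths_minor), collapse = ", "),
      paste(sprintf("%.3f", widths_major), collapse = ", ")
    )
  )

  bind_rows(out)
}

smoothing_widths_minor <- function(tau_s = c(0.5, 1, 2)) {
  grid <- make_grid(0, 25, 2500)
  input <- constant_plus_pulse(
    pulse_spec(1, 1, 10, 0.5), grid, "strain_rate",
    reference_scale = 1
  )
  vapply(tau_s, function(ts) {
    sens <- minor_sensor_params(K_s = 1, eta_s = ts)
    f <- force_from_strain_rate(input, sens)
    response_fwhm(f$time, f$value)
  }, numeric(1))
}

smoothing_widths_major <- function(tau_c = c(0.5, 1, 2)) {
  grid <- make_grid(0, 30, 3000)
  input <- constant_plus_pulse(
    pulse_spec(1, 1, 12, 0.5), grid, "strain_rate",
    reference_scale = 1
  )
  wall <- wall_params(1, 1, 1)
  seg <- segment_bond_params(0.01, 1, wall = wall)
  vapply(tau_c, function(tc) {
    law <- dissociation_law(tau_c = tc, F_c = Inf)
    pop <- population_response(input, wall, seg, law)
    response_fwhm(pop$time, pop$detach_force)
  }, numeric(1))
}
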