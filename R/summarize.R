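#' Local extrema with topographic prominence
#'
#' Finds strict local maxima (ties broken to the left sample) and computes
#' each peak's topographic prominence: the drop from the peak to the highest
#' of the two minima separating it from higher ground (or from the signal
#' ends). Only peaks with prominence at or above `min_prominence` are kept.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence (absolute units of `x`).
#' @return A tibble with columns `index`, `value`, `prominence`.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) {
    return(tibble(
      index = integer(0), value = numeric(0),
      prominence = numeric(0)
    ))
  }
  d <- diff(x)
  # indices i with x rising into i and falling after (plateaus: first sample)
  rising <- c(FALSE, d > 0)
  falling <- c(d < 0, FALSE)
  flat <- c(d == 0, FALSE)
  # carry "falling" backwards over flats so plateau starts count as peaks
  falls_next <- falling
  for (i in seq(n - 1, 1)) {
    if (flat[i]) falls_next[i] <- falls_next[i + 1]
  }
  cand <- which(rising & falls_next)
  if (length(cand) == 0) {
    return(tibble(
      index = integer(0), value = numeric(0),
      prominence = numeric(0)
    ))
  }
  prom <- vapply(cand, function(i) {
    v <- x[i]
    left <- x[1:i]
    higher_l <- which(left > v)
    lmin <- if (length(higher_l)) {
      min(left[max(higher_l):i])
    } else {
      min(left)
    }
    right <- x[i:n]
    higher_r <- which(right > v)
    rmin <- if (length(higher_r)) {
      min(right[1:min(higher_r)])
    } else {
      min(right)
    }
    v - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  tibble(index = cand[keep], value = x[cand[keep]], prominence = prom[keep])
}

#' Summarize a response trace: peaks, dips, steady levels
#'
#' Operationalizes the qualitative response signatures: peaks and dips of the
#' normalized output detected by topographic prominence (threshold expressed
#' as a fraction of the post-burn-in output range), pre- and post-pulse
#' steady levels (medians of the first and last 10% of the window), and the
#' largest sample-to-sample jump of the output (the "discontinuity" of the
#' low-F_c elastic regime).
#'
#' @param trace A `ws_response`/`ws_population` trace with `time` and
#'   `output` columns, at least 50 points.
#' @param prominence Prominence threshold as a fraction of the output range
#'   (default 0.02 = 2%).
#' @param burn_in Initial time span to exclude (same unit as `time`).
#' @return A one-row `ws_trace_summary` tibble with `n_peaks`, `n_dips`,
#'   list-columns of peak/dip times and prominences, `steady_pre`,
#'   `steady_post`, `max_abs_discontinuity` and `discontinuity_time`.
#' @export
summarize_trace <- function(trace, prominence = 0.02, burn_in = 0) {
  stopifnot(is.data.frame(trace), all(c("time", "output") %in% names(trace)))
  keep <- trace$time >= trace$time[1] + burn_in
  t <- trace$time[keep]
  y <- trace$output[keep]
  if (length(y) < 50) {
    abort("Trace too short to summarize (need >= 50 points after burn-in).",
      class = "wallsense_short_trace"
    )
  }
  rng <- diff(range(y))
  thr <- prominence * rng
  peaks <- find_peaks(y, thr)
  dips <- find_peaks(-y, thr)
  m <- max(1L, floor(length(y) * 0.1))
  jumps <- abs(diff(y))
  jmax <- which.max(jumps)
  out <- new_tibble(
    list(
      n_peaks = nrow(peaks),
      n_dips = nrow(dips),
      peak_times = list(t[peaks$index]),
      peak_values = list(peaks$value),
      peak_prominences = list(peaks$prominence),
      dip_times = list(t[dips$index]),
      dip_values = list(-dips$value),
      dip_prominences = list(dips$prominence),
      steady_pre = median(y[1:m]),
      steady_post = median(y[(length(y) - m + 1):length(y)]),
      max_abs_discontinuity = jumps[jmax],
      discontinuity_time = (t[jmax] + t[jmax + 1]) / 2,
      output_range = rng
    ),
    nrow = 1L, class = "ws_trace_summary"
  )
  attr(out, "prominence") <- prominence
  out
}

#' Full width at half maximum of a pulse-like trace
#'
#' Measures the width of the response peak above its pre-pulse baseline: the
#' baseline is the median of the first 10% of the trace, the half level lies
#' midway between baseline and maximum, and the crossing times are found by
#' linear interpolation. Used to quantify how much a sensor smooths a
#' strain-rate pulse.
#'
#' @param time,y Numeric vectors (trace samples).
#' @return The FWHM (time units), or `NA` if no crossing brackets the peak.
#' @export
response_fwhm <- function(time, y) {
  m <- max(1L, floor(length(y) * 0.1))
  base <- median(y[1:m])
  ipk <- which.max(y)
  half <- base + (y[ipk] - base) / 2
  above <- y >= half
  if (!above[ipk]) {
    return(NA_real_)
  }
  left <- ipk
  while (left > 1 && above[left - 1]) left <- left - 1
  right <- ipk
  while (right < length(y) && above[right + 1]) right <- right + 1
  t_left <- if (left == 1) {
    time[1]
  } else {
    approx(y[(left - 1):left], time[(left - 1):left], xout = half)$y
  }
  t_right <- if (right == length(y)) {
    time[right]
  } else {
    approx(y[right:(right + 1)], time[right:(right + 1)], xout = half)$y
  }
  t_right - t_left
}
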