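#' Tidy a response trace
#'
#' Returns the trace as a plain tibble in long-friendly wide form (`time`,
#' normalized `input` and `output`, plus any raw columns).
#'
#' @param x A `ws_response` or `ws_population` trace.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ws_response
#' @export
tidy.ws_response <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a response trace
#'
#' [summarize_trace()] as a `glance()` method: peak/dip counts, steady
#' levels, and the largest output jump.
#'
#' @param x A `ws_response` or `ws_population` trace.
#' @param ... Passed to [summarize_trace()].
#' @return A one-row tibble.
#' @method glance ws_response
#' @export
glance.ws_response <- function(x, ...) {
  s <- summarize_trace(x, ...)
  tibble(
    n_peaks = s$n_peaks, n_dips = s$n_dips,
    steady_pre = s$steady_pre, steady_post = s$steady_post,
    max_abs_discontinuity = s$max_abs_discontinuity,
    discontinuity_time = s$discontinuity_time
  )
}

#' Tidy an ensemble: the detachment-event list
#'
#' @param x A [simulate_ensemble()] result.
#' @param ... Unused.
#' @return A tibble with `time`, `force`, `sensor`.
#' @method tidy ws_ensemble
#' @export
tidy.ws_ensemble <- function(x, ...) {
  x$events
}

#' One-row summary of an ensemble
#'
#' @param x A [simulate_ensemble()] result.
#' @param ... Unused.
#' @return A one-row tibble with the event count, per-sensor event rate,
#'   mean detachment force, and seed.
#' @method glance ws_ensemble
#' @export
glance.ws_ensemble <- function(x, ...) {
  span <- x$t1 - x$t0
  tibble(
    n_sensors = x$n_sensors,
    n_events = nrow(x$events),
    event_rate = nrow(x$events) / (x$n_sensors * span),
    mean_force = mean(x$events$force),
    seed = x$seed
  )
}
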