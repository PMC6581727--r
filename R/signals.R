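#' Uniform time grid
#'
#' All simulation in wallsense happens on uniform time grids. `make_grid()`
#' builds one; the step `dt = (t1 - t0) / n_steps` must resolve the fastest
#' time scale of the scenario (see [check_resolution()]).
#'
#' @param t0,t1 Start and end time (same time unit as the rest of the
#'   scenario; presets work in units of the reference time).
#' @param n_steps Number of uniform steps; the grid has `n_steps + 1` points.
#' @return A `ws_grid` object: a list with `t0`, `t1`, `n_steps`, `dt` and the
#'   vector of grid times `time`.
#' @examples
#' g <- make_grid(0, 10, 100)
#' g$dt
#' @export
make_grid <- function(t0, t1, n_steps) {
  stopifnot(is.numeric(t0), is.numeric(t1), is.numeric(n_steps))
  if (!is.finite(t0) || !is.finite(t1) || t1 <= t0) {
    abort("`t1` must be greater than `t0`.", class = "wallsense_bad_grid")
  }
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 2) {
    abort("`n_steps` must be an integer >= 2.", class = "wallsense_bad_grid")
  }
  dt <- (t1 - t0) / n_steps
  structure(
    list(
      t0 = t0, t1 = t1, n_steps = n_steps, dt = dt,
      time = t0 + dt * (0:n_steps)
    ),
    class = "ws_grid"
  )
}

#' @export
print.ws_grid <- function(x, ...) {
  cat(sprintf(
    "<ws_grid> [%g, %g], %d steps, dt = %g\n",
    x$t0, x$t1, x$n_steps, x$dt
  ))
  invisible(x)
}

#' Check that a grid resolves a time scale
#'
#' The explicit quadrature used by the renewal solver and the sensor-branch
#' integrator is only trustworthy when `dt` is small against the fastest
#' relaxation/lifetime scale. The rule is `dt <= tau / 20`.
#'
#' @param grid A [make_grid()] object.
#' @param tau The time scale that must be resolved (e.g. `min(tau_s, tau_c,
#'   pulse width)`).
#' @param what Label used in the message.
#' @param on_coarse `"warning"` (default) or `"error"`; the default can be set
#'   globally via `options(wallsense.coarse_grid = "error")`.
#' @return `TRUE` (invisibly) when the grid resolves `tau`.
#' @export
check_resolution <- function(grid, tau, what = "time scale",
                             on_coarse = getOption("wallsense.coarse_grid", "warning")) {
  stopifnot(inherits(grid, "ws_grid"), is.numeric(tau), tau > 0)
  on_coarse <- arg_match0(on_coarse, c("warning", "error"))
  if (grid$dt > tau / 20) {
    msg <- sprintf(
      "Grid step dt = %g does not resolve %s = %g (need dt <= %g).",
      grid$dt, what, tau, tau / 20
    )
    if (on_coarse == "error") {
      abort(msg, class = "wallsense_coarse_grid")
    }
    warn(msg, class = "wallsense_coarse_grid")
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

ws_signal_kinds <- c(
  "stress", "strain", "strain_rate", "force", "rate", "probability"
)

#' Construct a mechanical signal
#'
#' A signal is a tibble with columns `time` and `value` plus metadata: the
#' signal kind (stress, strain, strain rate, force, or rate), a positive
#' reference scale used for normalization (sigma_0 for stress, 1/tau_0 for
#' strain rate, F_0 for force, 1/tau_c for rate), and an additive offset
#' subtracted before scaling (the yield threshold Y for stress in a growing
#' wall, 0 otherwise).
#'
#' @param time,value Numeric vectors of equal length.
#' @param kind One of `"stress"`, `"strain"`, `"strain_rate"`, `"force"`,
#'   `"rate"`.
#' @param reference_scale Positive reference scale for normalization.
#' @param offset Offset subtracted before scaling when normalizing.
#' @param units Free-text unit tag (internally everything is dimensionless).
#' @param normalized Logical; `TRUE` when `value` is already the normalized
#'   view `(raw - offset) / reference_scale`.
#' @return A `ws_signal` tibble.
#' @export
ws_signal <- function(time, value, kind, reference_scale = 1, offset = 0,
                      units = "dimensionless", normalized = FALSE) {
  kind <- arg_match0(kind, ws_signal_kinds)
  stopifnot(is.numeric(time), is.numeric(value))
  if (length(time) != length(value)) {
    abort("`time` and `value` must have the same length.",
      class = "wallsense_bad_signal"
    )
  }
  if (!is.numeric(reference_scale) || length(reference_scale) != 1 ||
    !is.finite(reference_scale) || reference_scale <= 0) {
    abort("`reference_scale` must be a single positive number.",
      class = "wallsense_bad_signal"
    )
  }
  out <- new_tibble(
    list(time = as.double(time), value = as.double(value)),
    nrow = length(time),
    class = "ws_signal"
  )
  attr(out, "kind") <- kind
  attr(out, "reference_scale") <- as.double(reference_scale)
  attr(out, "offset") <- as.double(offset)
  attr(out, "units") <- units
  attr(out, "normalized") <- isTRUE(normalized)
  out
}

signal_from_grid <- function(grid, value, kind, reference_scale = 1,
                             offset = 0, units = "dimensionless") {
  stopifnot(inherits(grid, "ws_grid"))
  ws_signal(grid$time, value, kind,
    reference_scale = reference_scale,
    offset = offset, units = units
  )
}

#' @export
print.ws_signal <- function(x, ...) {
  cat(sprintf(
    "<ws_signal> kind = %s, %d points, reference_scale = %g, offset = %g%s\n",
    signal_kind(x), nrow(x), reference_scale(x), signal_offset(x),
    if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""
  ))
  NextMethod()
}

#' Signal metadata accessors
#'
#' @param signal A [ws_signal()].
#' @return `signal_kind()` the kind string; `reference_scale()` and
#'   `signal_offset()` the normalization constants; `signal_grid()` the
#'   implied uniform [make_grid()] object; `signal_dt()` the grid step.
#' @name signal-accessors
NULL

#' @rdname signal-accessors
#' @export
signal_kind <- function(signal) attr(signal, "kind")

#' @rdname signal-accessors
#' @export
reference_scale <- function(signal) attr(signal, "reference_scale")

#' @rdname signal-accessors
#' @export
signal_offset <- function(signal) attr(signal, "offset")

#' @rdname signal-accessors
#' @export
signal_dt <- function(signal) {
  dt <- diff(signal$time)
  if (length(dt) == 0) abort("Signal has fewer than 2 points.")
  if (diff(range(dt)) > 1e-9 * max(abs(dt))) {
    abort("Signal grid is not uniform.", class = "wallsense_bad_signal")
  }
  mean(dt)
}

#' @rdname signal-accessors
#' @export
signal_grid <- function(signal) {
  n <- nrow(signal) - 1L
  make_grid(signal$time[1], signal$time[nrow(signal)], n)
}

check_kind <- function(signal, kind, arg = "signal") {
  if (!inherits(signal, "ws_signal")) {
    abort(sprintf("`%s` must be a ws_signal.", arg),
      class = "wallsense_kind_mismatch"
    )
  }
  if (!identical(signal_kind(signal), kind)) {
    abort(
      sprintf(
        "`%s` must have kind '%s', got '%s'.", arg, kind, signal_kind(signal)
      ),
      class = "wallsense_kind_mismatch"
    )
  }
  invisible(TRUE)
}

#' Pulse specification: constant background plus a transient peak
#'
#' The canonical input of all scenarios: a constant background (the
#' turgor-generated stress, or the steady expansion rate) with one transient
#' peak (a transient external load such as bending). The peak is parameterized
#' by its full width at half maximum.
#'
#' @param baseline Background level.
#' @param amplitude Peak height above the baseline (0 gives a constant input).
#' @param center Peak time.
#' @param width Full width at half maximum (FWHM), must be positive.
#' @param shape `"gaussian"` (default, smooth, so the stress rate stays
#'   well-defined) or `"raised_cosine"` (compact support `center +- width`).
#' @return A `ws_pulse` list.
#' @export
pulse_spec <- function(baseline, amplitude, center, width,
                       shape = c("gaussian", "raised_cosine")) {
  shape <- arg_match(shape)
  stopifnot(
    is.numeric(baseline), is.numeric(amplitude),
    is.numeric(center), is.numeric(width)
  )
  if (!is.finite(width) || width <= 0) {
    abort("`width` (FWHM) must be positive.", class = "wallsense_bad_pulse")
  }
  structure(
    list(
      baseline = baseline, amplitude = amplitude, center = center,
      width = width, shape = shape
    ),
    class = "ws_pulse"
  )
}

#' @export
print.ws_pulse <- function(x, ...) {
  cat(sprintf(
    "<ws_pulse> %s: baseline %g + amplitude %g, center %g, FWHM %g\n",
    x$shape, x$baseline, x$amplitude, x$center, x$width
  ))
  invisible(x)
}

pulse_shape_value <- function(x, shape) {
  # x = (t - center) / width, width = FWHM: shape(1/2) = 1/2 for both forms
  switch(shape,
    gaussian = exp(-4 * log(2) * x^2),
    raised_cosine = ifelse(abs(x) < 1, 0.5 * (1 + cos(pi * x)), 0),
    abort(sprintf("Unknown pulse shape '%s'.", shape),
      class = "wallsense_bad_pulse"
    )
  )
}

#' Sample a background-plus-pulse input on a grid
#'
#' @param spec A [pulse_spec()].
#' @param grid A [make_grid()] grid.
#' @inheritParams ws_signal
#' @return A `ws_signal` with
#'   `value = baseline + amplitude * shape((t - center)/width)`.
#' @examples
#' g <- make_grid(0, 20, 400)
#' sig <- constant_plus_pulse(pulse_spec(1, 1, 10, 0.5), g, "stress",
#'   reference_scale = 1
#' )
#' @export
constant_plus_pulse <- function(spec, grid, kind, reference_scale = 1,
                                offset = 0, units = "dimensionless") {
  stopifnot(inherits(spec, "ws_pulse"), inherits(grid, "ws_grid"))
  x <- (grid$time - spec$center) / spec$width
  value <- spec$baseline + spec$amplitude * pulse_shape_value(x, spec$shape)
  signal_from_grid(grid, value, kind,
    reference_scale = reference_scale,
    offset = offset, units = units
  )
}

#' Normalize / denormalize a signal
#'
#' `normalize()` returns the dimensionless view `(value - offset) /
#' reference_scale` (for stress the offset is typically the yield threshold Y,
#' so normalized stress is `(sigma - Y)/sigma_0`); `denormalize()` inverts it.
#' The round trip is the identity to machine precision.
#'
#' @param signal A [ws_signal()].
#' @param offset Optional override of the signal's stored offset.
#' @return A `ws_signal` flagged as normalized (or raw again).
#' @export
normalize <- function(signal, offset = NULL) {
  stopifnot(inherits(signal, "ws_signal"))
  if (isTRUE(attr(signal, "normalized"))) {
    return(signal)
  }
  scale <- reference_scale(signal)
  if (is.null(scale) || !is.finite(scale) || scale <= 0) {
    abort("Signal has no valid reference_scale.", class = "wallsense_bad_signal")
  }
  off <- if (is.null(offset)) signal_offset(signal) else offset
  ws_signal(signal$time, (signal$value - off) / scale,
    kind = signal_kind(signal), reference_scale = scale, offset = off,
    units = "dimensionless", normalized = TRUE
  )
}

#' @rdname normalize
#' @export
denormalize <- function(signal) {
  stopifnot(inherits(signal, "ws_signal"))
  if (!isTRUE(attr(signal, "normalized"))) {
    return(signal)
  }
  scale <- reference_scale(signal)
  off <- signal_offset(signal)
  ws_signal(signal$time, signal$value * scale + off,
    kind = signal_kind(signal), reference_scale = scale, offset = off,
    units = attr(signal, "units"), normalized = FALSE
  )
}

#' Numerical time derivative of a signal
#'
#' Centered differences at interior points, second-order one-sided stencils at
#' the ends. Exact for constant and linear signals on a uniform grid; O(dt^2)
#' otherwise. Used for the elastic loading-rate term of the wall law.
#'
#' @param signal A [ws_signal()] with at least 3 points on a uniform grid.
#' @param kind Kind tag of the derivative signal; defaults follow the obvious
#'   pairs (`strain` -> `strain_rate`), else the input kind is kept.
#' @param reference_scale Reference scale of the derivative signal.
#' @return A `ws_signal` on the same grid.
#' @export
numerical_derivative <- function(signal, kind = NULL, reference_scale = 1) {
  stopifnot(inherits(signal, "ws_signal"))
  n <- nrow(signal)
  if (n < 3) {
    abort("Need at least 3 points to differentiate.",
      class = "wallsense_bad_signal"
    )
  }
  dt <- signal_dt(signal)
  v <- signal$value
  d <- numeric(n)
  # difference-of-differences forms so a constant differentiates to exactly 0
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (4 * (v[2] - v[1]) - (v[3] - v[1])) / (2 * dt)
  d[n] <- (4 * (v[n] - v[n - 1]) - (v[n] - v[n - 2])) / (2 * dt)
  if (is.null(kind)) {
    kind <- switch(signal_kind(signal),
      strain = "strain_rate",
      signal_kind(signal)
    )
  }
  ws_signal(signal$time, d,
    kind = kind, reference_scale = reference_scale,
    units = "per time"
  )
}

#' Trapezoidal cumulative integral of a signal
#'
#' @param signal A [ws_signal()].
#' @param init Value of the integral at the first grid point.
#' @param kind Kind tag of the integrated signal (`strain_rate` -> `strain`
#'   by default).
#' @param reference_scale Reference scale of the integrated signal.
#' @return A `ws_signal` on the same grid.
#' @export
cumulative_integral <- function(signal, init = 0, kind = NULL,
                                reference_scale = 1) {
  stopifnot(inherits(signal, "ws_signal"))
  dt <- signal_dt(signal)
  v <- signal$value
  n <- length(v)
  inc <- dt * (v[-n] + v[-1]) / 2
  out <- init + c(0, cumsum(inc))
  if (is.null(kind)) {
    kind <- switch(signal_kind(signal),
      strain_rate = "strain",
      signal_kind(signal)
    )
  }
  ws_signal(signal$time, out, kind = kind, reference_scale = reference_scale)
}

#' Read / write signals as annotated CSV
#'
#' The on-disk dialect is plain CSV with `time,value` rows preceded by header
#' comment lines `# kind=...`, `# reference_scale=...`, `# offset=...`,
#' `# units=...`, `# normalized=...`. Values are written with 17 significant
#' digits so the round trip is exact.
#'
#' @param signal A [ws_signal()].
#' @param path File path.
#' @return `write_signal_csv()` returns `path` invisibly; `read_signal_csv()`
#'   returns the `ws_signal`.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ws_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kind=%s", signal_kind(signal)),
    sprintf("# reference_scale=%.17g", reference_scale(signal)),
    sprintf("# offset=%.17g", signal_offset(signal)),
    sprintf("# units=%s", attr(signal, "units")),
    sprintf("# normalized=%s", isTRUE(attr(signal, "normalized"))),
    "time,value",
    sprintf("%.17g,%.17g", signal$time, signal$value)
  ), con)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^# ", lines)]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  ws_signal(dat$time, dat$value,
    kind = meta$kind %||% "stress",
    reference_scale = as.numeric(meta$reference_scale %||% "1"),
    offset = as.numeric(meta$offset %||% "0"),
    units = meta$units %||% "dimensionless",
    normalized = identical(meta$normalized, "TRUE")
  )
}
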