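#' Plot a mechanical signal
#'
#' @param object A [ws_signal()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ws_signal
#' @export
autoplot.ws_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(
      x = "time", y = signal_kind(object),
      title = sprintf("%s signal", signal_kind(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a response trace (normalized input and output)
#'
#' Input in blue, sensor output in green, as in the model figures.
#'
#' @param object A `ws_response` or `ws_population` trace with normalized
#'   `input` and `output` columns.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ws_response
#' @export
autoplot.ws_response <- function(object, ...) {
  dat <- tibble(
    time = rep(object$time, 2),
    value = c(object$input, object$output),
    series = rep(c("input", "output"), each = nrow(object))
  )
  sc <- attr(object, "scenario")
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$time, y = .data$value, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(input = "#2166ac", output = "#1a9850")
    ) +
    ggplot2::labs(
      x = "time (reference units)", y = "normalized value",
      title = if (!is.null(sc)) sc$name else attr(object, "trace_kind")
    ) +
    ggplot2::theme_minimal()
}

#' Plot binned ensemble estimates against the renewal solution
#'
#' @param object A [simulate_ensemble()] result.
#' @param pop Optional [population_response()] trace to overlay.
#' @param what `"rate"` or `"mean_force"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ws_ensemble
#' @export
autoplot.ws_ensemble <- function(object, pop = NULL,
                                 what = c("rate", "mean_force"), ...) {
  what <- arg_match(what)
  b <- object$binned
  p <- ggplot2::ggplot(
    b, ggplot2::aes(x = .data$t_mid, y = .data[[what]])
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data[[what]] - .data[[paste0(
          sub("mean_", "", what), "_se"
        )]],
        ymax = .data[[what]] + .data[[paste0(
          sub("mean_", "", what), "_se"
        )]]
      ),
      size = 0.2, colour = "grey40"
    ) +
    ggplot2::labs(
      x = "time", y = what,
      title = sprintf("ensemble (%d sensors)", object$n_sensors)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(pop)) {
    col <- if (what == "rate") "rate" else "detach_force"
    p <- p + ggplot2::geom_line(
      data = tibble(t_mid = pop$time, y = pop[[col]]),
      ggplot2::aes(y = .data$y),
      colour = "#1a9850"
    )
  }
  p
}
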