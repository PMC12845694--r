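#' Respiratory displacement signals
#'
#' A `resp_signal` is a tibble with columns `time_s` and `displacement_mm`
#' holding a uniformly sampled 1-D respiratory displacement trace, plus two
#' attributes: `dt` (the sample interval in seconds) and `meta` (a named list
#' of free-form labels such as the generating pattern or seed). All simulator,
#' filter and gating functions take and return this shape, so calls chain with
#' the pipe.
#'
#' @param values Numeric vector of displacement samples \[mm\]. Must be finite
#'   and non-empty.
#' @param dt Sample interval \[s\], > 0. Default 0.01 s (100 Hz, the sampling
#'   rate of typical optical tracking systems).
#' @param t0 Time of the first sample \[s\].
#' @param meta Named list of free-form labels carried along with the signal.
#'
#' @return A tibble of class `resp_signal` with columns `time_s`,
#'   `displacement_mm`.
#' @examples
#' s <- resp_signal(sin(2 * pi * seq(0, 10, by = 0.01) / 5) * 10)
#' signal_dt(s)
#' @export
resp_signal <- function(values, dt = 0.01, t0 = 0, meta = list()) {
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(t0, "t0")
  values <- as.numeric(values)
  if (length(values) < 1L) {
    abort("a `resp_signal` needs at least one sample.")
  }
  if (!all(is.finite(values))) {
    abort(sprintf(
      "non-finite displacement at sample %d.",
      which(!is.finite(values))[1L]
    ))
  }
  new_resp_signal(
    tibble::tibble(
      time_s = t0 + dt * (seq_along(values) - 1L),
      displacement_mm = values
    ),
    dt = dt, meta = meta
  )
}

new_resp_signal <- function(df, dt, meta = list()) {
  stopifnot(is.data.frame(df))
  structure(
    tibble::as_tibble(df),
    dt = dt,
    meta = meta,
    class = c("resp_signal", class(tibble::tibble()))
  )
}

#' @rdname resp_signal
#' @param x A `resp_signal`.
#' @export
signal_dt <- function(x) {
  attr(x, "dt") %||% {
    tt <- x$time_s
    if (length(tt) > 1L) median(diff(tt)) else 0.01
  }
}

#' @rdname resp_signal
#' @export
signal_meta <- function(x) {
  attr(x, "meta") %||% list()
}

# Replace the sample values, preserving time base and meta.
set_values <- function(x, values, extra_meta = list()) {
  meta <- modifyList(signal_meta(x), extra_meta)
  new_resp_signal(
    tibble::tibble(time_s = x$time_s, displacement_mm = as.numeric(values)),
    dt = signal_dt(x), meta = meta
  )
}

#' @export
print.resp_signal <- function(x, ...) {
  dt <- signal_dt(x)
  meta <- signal_meta(x)
  cat(sprintf(
    "<resp_signal> %d samples @ %.4g Hz (%.4g s)%s\n",
    nrow(x), 1 / dt, nrow(x) * dt,
    if (length(meta)) paste0(
      " [", paste(names(meta), unlist(lapply(meta, format)), sep = "=", collapse = ", "), "]"
    ) else ""
  ))
  NextMethod()
}

#' @export
autoplot.resp_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$displacement_mm)) +
    ggplot2::geom_line(colour = "#2c6e91") +
    ggplot2::labs(x = "time [s]", y = "displacement [mm]") +
    ggplot2::theme_minimal()
}
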