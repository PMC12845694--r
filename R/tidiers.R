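# broom-style tidiers for fitted objects.

#' Tidy the per-step trace of a filter fit
#'
#' @param x A [run_filter()] result.
#' @param ... Unused.
#' @return The per-step trace tibble (`time_s`, `z_mm`, `xr_mm`, `vr_mms`,
#'   `c_mm`, `fr_hz`, `innovation_mm`, `pred_mm`).
#' @exportS3Method generics::tidy
tidy.resp_kf <- function(x, ...) {
  x$trace
}

#' One-row summary of a filter fit
#'
#' @param x A [run_filter()] result.
#' @param ... Unused.
#' @return Tibble with `n`, `dt_s`, `fr_hz` (settled frequency),
#'   `innovation_sd_mm` and `innovation_lag1_acf` (both after a 5 s burn-in)
#'   and `horizon_steps`.
#' @exportS3Method generics::glance
glance.resp_kf <- function(x, ...) {
  nu <- x$trace$innovation_mm
  burn <- min(length(nu), max(1L, round(5 / x$config$dt)))
  nu_s <- nu[burn:length(nu)]
  lag1 <- if (length(nu_s) > 10L) {
    unname(acf(nu_s, lag.max = 1, plot = FALSE)$acf[2L])
  } else {
    NA_real_
  }
  tibble::tibble(
    n = nrow(x$trace),
    dt_s = x$config$dt,
    fr_hz = x$trace$fr_hz[nrow(x$trace)],
    innovation_sd_mm = sd(nu_s),
    innovation_lag1_acf = lag1,
    horizon_steps = x$config$horizon_steps
  )
}

#' Tidy gating events
#'
#' @param x A [run_gating()] result.
#' @param ... Unused.
#' @return A plain tibble of emitted events.
#' @exportS3Method generics::tidy
tidy.resp_gating <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a gating run
#'
#' @param x A [run_gating()] result.
#' @param ... Unused.
#' @return Tibble with event counts, mode and latency.
#' @exportS3Method generics::glance
glance.resp_gating <- function(x, ...) {
  cand <- attr(x, "candidates")
  tibble::tibble(
    n_events = nrow(x),
    n_candidates = if (is.null(cand)) NA_integer_ else nrow(cand),
    n_suppressed = if (is.null(cand)) NA_integer_ else sum(!cand$valid),
    mode = attr(x, "mode"),
    latency_s = attr(x, "latency_s")
  )
}

#' Tidy a rigid transform
#'
#' @param x A [umeyama_rigid()] result.
#' @param ... Unused.
#' @return Long tibble of transform parameters (rotation entries row-major,
#'   translation components, scale).
#' @exportS3Method generics::tidy
tidy.rigid_transform <- function(x, ...) {
  tibble::tibble(
    term = c(sprintf("r%d%d", rep(1:3, each = 3), rep(1:3, 3)),
             c("tx_mm", "ty_mm", "tz_mm"), "scale"),
    estimate = c(as.numeric(t(x$R)), x$t, x$scale %||% 1)
  )
}

#' One-row summary of a rigid registration
#'
#' @param x A [umeyama_rigid()] result.
#' @param ... Unused.
#' @return Tibble with `n`, `rmse_mm`, `scale`, rotation angle \[deg\] and
#'   determinant.
#' @exportS3Method generics::glance
glance.rigid_transform <- function(x, ...) {
  ang <- acos(max(min((sum(diag(x$R)) - 1) / 2, 1), -1)) * 180 / pi
  tibble::tibble(
    n = x$n %||% NA_integer_,
    rmse_mm = x$rmse %||% NA_real_,
    scale = x$scale %||% 1,
    angle_deg = ang,
    det = det(x$R)
  )
}

#' Tidy / summarise a mode-comparison evaluation
#'
#' @param x A [compare_modes()] result.
#' @param ... Unused.
#' @return `tidy()`: the two-row per-mode report; `glance()`: one row with
#'   the headline mode contrast (TPE means and `Delta_T` means).
#' @exportS3Method generics::tidy
tidy.resp_eval <- function(x, ...) {
  x$report
}

#' @rdname tidy.resp_eval
#' @exportS3Method generics::glance
glance.resp_eval <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    tpe_mean_a_mm = r$tpe_mean[r$mode == "A"],
    tpe_mean_b_mm = r$tpe_mean[r$mode == "B"],
    dt_mean_a_ms = r$dt_mean_ms[r$mode == "A"],
    dt_mean_b_ms = r$dt_mean_ms[r$mode == "B"],
    accuracy_a_pct = r$accuracy_pct[r$mode == "A"],
    accuracy_b_pct = r$accuracy_pct[r$mode == "B"],
    n_cycles = length(x$gold)
  )
}
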