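#' Adaptive Kalman filter configuration
#'
#' Tunable parameters of the harmonic state-space filter. The state is
#' `x = (Xr, Vr, C)`: respiratory displacement \[mm\], its velocity \[mm/s\]
#' and a slowly varying baseline offset \[mm\]. The transition matrix encodes
#' a local harmonic oscillator at the current smoothed breathing frequency;
#' the measurement is `z = Xr + C + noise`.
#'
#' @param dt Sample interval \[s\] (default 0.01 s, 100 Hz optical tracking).
#' @param f0 Initial breathing-frequency guess \[Hz\] (default 0.2 Hz =
#'   12 breaths/min, mid resting range).
#' @param f_min,f_max Frequency clamp \[Hz\]; generous around the 10-20
#'   breaths/min physiologic range.
#' @param freq_buffer_s Length of the filtered-signal buffer used for
#'   peak-based frequency estimation \[s\].
#' @param iir_cutoff_hz Cutoff of the one-pole IIR low-pass applied per sample
#'   to the raw frequency estimate \[Hz\].
#' @param alpha Scale of the baseline process noise relative to the long-term
#'   respiration variance (Q's third diagonal = `alpha * sigma2_resp`).
#' @param q0 First process-noise diagonal (displacement channel) \[mm^2\].
#' @param resp_buffer_s Long-term buffer over which the respiration variance
#'   `sigma2_resp` is computed \[s\].
#' @param noise_window_s Window over which the measurement-noise sd is
#'   estimated from first differences of the raw stream \[s\].
#' @param horizon_steps Maximum multi-step prediction horizon `H_max`
#'   (default 14 steps = 140 ms at 100 Hz, matching the anticipatory prompt
#'   lead).
#' @param freq_update_every How often (in samples) the raw peak-based
#'   frequency, noise sd and respiration variance are re-estimated; the IIR
#'   smoothing still runs every sample.
#' @return A list of class `kf_config`.
#' @export
kf_config <- function(dt = 0.01, f0 = 0.2, f_min = 0.05, f_max = 1.0,
                      freq_buffer_s = 20, iir_cutoff_hz = 0.05,
                      alpha = 0.01, q0 = 1, resp_buffer_s = 60,
                      noise_window_s = 5, horizon_steps = 14,
                      freq_update_every = 25) {
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(alpha, "alpha", positive = TRUE)
  if (!(f_min > 0 && f_min <= f0 && f0 <= f_max)) {
    abort("need 0 < f_min <= f0 <= f_max.")
  }
  if (horizon_steps < 1) {
    abort("`horizon_steps` must be >= 1.")
  }
  structure(
    list(
      dt = dt, f0 = f0, f_min = f_min, f_max = f_max,
      freq_buffer_s = freq_buffer_s, iir_cutoff_hz = iir_cutoff_hz,
      alpha = alpha, q0 = q0, resp_buffer_s = resp_buffer_s,
      noise_window_s = noise_window_s,
      horizon_steps = as.integer(horizon_steps),
      freq_update_every = as.integer(freq_update_every)
    ),
    class = "kf_config"
  )
}

#' State transition matrix of the harmonic respiratory model
#'
#' `A = [[1, dt, 0], [-omega^2 * dt, 1, 0], [0, 0, 1]]` with
#' `omega = 2 * pi * f_r`: an Euler discretisation of a harmonic oscillator in
#' `(Xr, Vr)` with a random-walk baseline `C`.
#'
#' @param f_r Breathing frequency \[Hz\], > 0.
#' @param dt Time step \[s\], >= 0.
#' @return A 3x3 transition matrix.
#' @examples
#' kf_transition(0.2, 0.01)
#' @export
kf_transition <- function(f_r, dt) {
  check_scalar(f_r, "f_r", positive = TRUE)
  check_scalar(dt, "dt", nonneg = TRUE)
  w <- 2 * pi * f_r
  matrix(c(
    1, dt, 0,
    -w^2 * dt, 1, 0,
    0, 0, 1
  ), nrow = 3, byrow = TRUE)
}

# Observation row vector: z = Xr + C + noise.
kf_observation <- function() matrix(c(1, 0, 1), nrow = 1)

#' Adaptive process-noise covariance
#'
#' `Q = diag(q0, omega_r^2, alpha * sigma2_resp)`: the velocity channel noise
#' scales with the squared breathing frequency and the baseline channel with a
#' small fraction of the long-term respiration variance.
#'
#' @param omega_r Angular breathing frequency \[rad/s\].
#' @param sigma2_resp Long-term variance of the filtered respiratory
#'   displacement \[mm^2\], >= 0.
#' @param alpha Baseline noise fraction (default 0.01).
#' @param q0 Displacement-channel noise (default 1).
#' @return A 3x3 diagonal matrix.
#' @examples
#' kf_process_noise(2 * pi * 0.2, 25)
#' @export
kf_process_noise <- function(omega_r, sigma2_resp, alpha = 0.01, q0 = 1) {
  check_scalar(sigma2_resp, "sigma2_resp", nonneg = TRUE)
  diag(c(q0, omega_r^2, alpha * sigma2_resp))
}

#' Single Kalman prediction step
#'
#' Propagates the state mean and covariance one step through the transition
#' model: `x- = A x`, `P- = A P A' + Q`.
#'
#' @param state List with elements `x` (3-vector) and `P` (3x3 covariance).
#' @param A Transition matrix from [kf_transition()].
#' @param Q Process noise from [kf_process_noise()].
#' @return The predicted state (same shape).
#' @export
kf_predict <- function(state, A, Q) {
  if (!all(is.finite(state$x)) || !all(is.finite(state$P))) {
    abort("non-finite filter state.")
  }
  x <- as.numeric(A %*% state$x)
  P <- A %*% state$P %*% t(A) + Q
  modifyList(state, list(x = x, P = (P + t(P)) / 2))
}

#' Single Kalman measurement update (Joseph form)
#'
#' Scalar-measurement update with observation row `H = [1, 0, 1]`. The
#' covariance is updated in Joseph-stabilised form
#' `P = (I - K H) P- (I - K H)' + R K K'` so it stays symmetric positive
#' semidefinite over long runs.
#'
#' @param state Predicted state (list with `x`, `P`).
#' @param z Measured displacement \[mm\].
#' @param R Measurement noise variance \[mm^2\], > 0.
#' @return Updated state; elements `innovation` and `gain` are added.
#' @export
kf_update <- function(state, z, R) {
  check_scalar(R, "R", positive = TRUE)
  H <- kf_observation()
  x <- state$x
  P <- state$P
  S <- as.numeric(H %*% P %*% t(H)) + R
  K <- as.numeric(P %*% t(H)) / S
  nu <- z - as.numeric(H %*% x)
  B <- diag(3) - K %*% H
  Pn <- B %*% P %*% t(B) + R * (K %*% t(K))
  modifyList(state, list(
    x = x + K * nu, P = (Pn + t(Pn)) / 2, innovation = nu, gain = K
  ))
}

#' Multi-step-ahead prediction of the respiratory displacement
#'
#' Iterative propagation of the state model: `x_hat(k + h | k) = A^h x_k`,
#' returning the displacement component `[1, 0, 0] A^h x_k` for
#' `h = 1, ..., H_max` (the baseline `C` is untouched by the propagation and
#' excluded from the returned respiratory component).
#'
#' @param state List with state vector `x`.
#' @param A Transition matrix.
#' @param H_max Maximum horizon, >= 1.
#' @return Numeric vector of length `H_max`; element `h` is the predicted
#'   respiratory displacement `h` steps ahead \[mm\].
#' @export
kf_predict_ahead <- function(state, A, H_max) {
  if (H_max < 1) {
    abort("`H_max` must be >= 1.")
  }
  x <- state$x
  out <- numeric(H_max)
  for (h in seq_len(H_max)) {
    x <- as.numeric(A %*% x)
    out[h] <- x[1L]
  }
  out
}

# Closed form of the h-step propagation of the 2x2 oscillator block:
# A2 = [[1, dt], [-w^2 dt, 1]] = s * D R(theta) D^-1 with s = sqrt(1 + (w dt)^2),
# theta = atan(w dt), D = diag(1, w). Used by the filter loop and gating for
# speed; kf_predict_ahead() is the reference repeated-multiplication route.
osc_predict <- function(xr, vr, w, dt, h) {
  wdt <- w * dt
  s <- sqrt(1 + wdt^2)
  th <- atan(wdt)
  ch <- cos(h * th)
  sh <- sin(h * th)
  g <- s^h
  list(
    xr = g * (ch * xr + sh / w * vr),
    vr = g * (-w * sh * xr + ch * vr)
  )
}

#' Estimate breathing frequency from a filtered-signal buffer
#'
#' Raw estimate: reciprocal of the mean peak-to-peak interval of prominent
#' peaks in the buffer (prominence >= 20% of the buffer's peak-to-peak range,
#' separation >= `1 / f_max`). The raw value is smoothed by a one-pole IIR
#' low-pass (`y <- y + a * (raw - y)`, `a = 1 - exp(-2 pi f_c dt)`) applied
#' `n_steps` times (once per new sample in streaming use), then clamped to
#' `[f_min, f_max]`. With fewer than two peaks `prev_f` is returned unchanged.
#'
#' @param buffer A [resp_signal()] or numeric vector of filtered displacement
#'   (most recent `freq_buffer_s` seconds).
#' @param config A [kf_config()] (supplies dt, cutoff and clamp).
#' @param prev_f Previous smoothed estimate \[Hz\].
#' @param n_steps Number of per-sample IIR iterations to apply.
#' @return Smoothed, clamped frequency estimate \[Hz\].
#' @export
estimate_frequency <- function(buffer, config = kf_config(), prev_f = config$f0,
                               n_steps = 1L) {
  v <- if (is.data.frame(buffer)) buffer$displacement_mm else as.numeric(buffer)
  dt <- config$dt
  raw <- raw_frequency(v, dt, config$f_max)
  if (is.na(raw)) {
    return(prev_f)
  }
  a <- 1 - exp(-2 * pi * config$iir_cutoff_hz * dt)
  f <- prev_f + (raw - prev_f) * (1 - (1 - a)^n_steps)
  min(max(f, config$f_min), config$f_max)
}

raw_frequency <- function(v, dt, f_max) {
  if (length(v) < 3L) {
    return(NA_real_)
  }
  # decimate to ~25 Hz: peak-interval estimation needs no more resolution
  # (quantisation error < 0.5% of a breathing period) and the prominence
  # scan cost drops accordingly
  ds <- max(1L, floor(0.04 / dt))
  if (ds > 1L) {
    v <- v[seq(1L, length(v), by = ds)]
    dt <- dt * ds
  }
  if (length(v) < 3L) {
    return(NA_real_)
  }
  p2p <- diff(range(v))
  if (p2p <= .Machine$double.eps) {
    return(NA_real_)
  }
  pk <- find_peak_idx(v, min_sep = max(1L, round(1 / (f_max * dt))),
                      min_prom = 0.2 * p2p)
  if (length(pk) < 2L) {
    return(NA_real_)
  }
  1 / (mean(diff(pk)) * dt)
}

#' Estimate the measurement-noise standard deviation
#'
#' Uses the high-frequency content of the raw stream via numerical
#' differentiation: `sigma_noise = sd(diff(buffer)) / sqrt(2)` over the most
#' recent `noise_window_s` seconds. At 100 Hz the first difference of smooth
#' respiration is negligible relative to i.i.d. noise, so the estimate
#' isolates the sensor noise. Floored at 1e-6 mm.
#'
#' @param buffer A [resp_signal()] or numeric vector of raw measurements.
#' @param config A [kf_config()].
#' @param prev Previous estimate, returned when the buffer is shorter than 10
#'   samples (floor at cold start).
#' @return Noise sd \[mm\].
#' @export
estimate_noise_sd <- function(buffer, config = kf_config(), prev = NULL) {
  v <- if (is.data.frame(buffer)) buffer$displacement_mm else as.numeric(buffer)
  if (length(v) < 10L) {
    return(prev %||% 1e-6)
  }
  n_win <- max(10L, round(config$noise_window_s / config$dt))
  v <- tail(v, n_win)
  max(sd(diff(v)) / sqrt(2), 1e-6)
}

#' Run the adaptive Kalman filter over a measured signal
#'
#' Strictly causal streaming estimation: at each step the breathing frequency
#' (peak detection over a `freq_buffer_s` buffer of the filtered signal,
#' one-pole IIR smoothing), the measurement-noise variance `R` (first
#' differences of the raw stream) and the process noise `Q` are re-estimated
#' from samples up to the current one, then a predict/update cycle is applied
#' and the state is propagated `horizon_steps` ahead.
#'
#' Initialisation: `x0 = (z0 - m, 0, m)` with `m` the median of the first two
#' seconds (the slow offset is assigned to the baseline channel), and
#' `P0 = diag(25, 25, 25)`.
#'
#' @param measured A [resp_signal()] measurement stream.
#' @param config A [kf_config()].
#' @return An object of class `resp_kf` with elements:
#'   * `trace`: tibble with per-step `time_s`, `z_mm`, `xr_mm`, `vr_mms`,
#'     `c_mm`, `fr_hz`, `innovation_mm` and `pred_mm` (predicted observable
#'     displacement at the maximum horizon);
#'   * `pred_xr`: n x `horizon_steps` matrix of respiratory-displacement
#'     predictions `X_hat(k + h | k)`;
#'   * `P`: n x 6 matrix of the covariance upper triangle
#'     (p11, p12, p13, p22, p23, p33);
#'   * `config`, `signal_meta`, `state` (final state).
#' @examples
#' fit <- sim_sine(duration_s = 30) |>
#'   add_noise(0.3, seed = 1) |>
#'   run_filter()
#' glance(fit)
#' @export
run_filter <- function(measured, config = kf_config()) {
  z <- measured$displacement_mm
  bad <- which(!is.finite(z))
  if (length(bad)) {
    abort(sprintf("non-finite measurement at sample %d.", bad[1L]))
  }
  n <- length(z)
  dt <- signal_dt(measured)
  if (abs(dt - config$dt) > 1e-9) {
    config$dt <- dt
  }
  H_max <- config$horizon_steps

  # --- initialisation (first 2 s assign the slow offset to C)
  m0 <- median(z[seq_len(min(n, max(1L, round(2 / dt))))])
  x1 <- z[1L] - m0
  x2 <- 0
  x3 <- m0
  p11 <- p22 <- p33 <- 25
  p12 <- p13 <- p23 <- 0

  f_r <- min(max(config$f0, config$f_min), config$f_max)
  raw_f <- f_r
  a_iir <- 1 - exp(-2 * pi * config$iir_cutoff_hz * dt)
  sigma_noise <- estimate_noise_sd(z[seq_len(min(n, max(10L, round(2 / dt))))],
                                   config, prev = 1e-6)
  sigma2_resp <- 25
  q0 <- config$q0
  alpha <- config$alpha

  n_freq_buf <- round(config$freq_buffer_s / dt)
  n_resp_buf <- round(config$resp_buffer_s / dt)
  upd_every <- max(1L, config$freq_update_every)

  xr_t <- vr_t <- c_t <- fr_t <- nu_t <- numeric(n)
  P_t <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("p11", "p12", "p13", "p22", "p23", "p33")))
  pred_xr <- matrix(NA_real_, n, H_max)
  hh <- seq_len(H_max)

  for (k in seq_len(n)) {
    # ---- adaptive re-estimation from causal buffers
    if (k == 1L || k %% upd_every == 0L) {
      lo <- max(1L, k - n_freq_buf)
      if (k > 2L) {
        rf <- raw_frequency(xr_t[lo:(k - 1L)], dt, config$f_max)
        if (!is.na(rf)) raw_f <- rf
      }
      if (k > 10L) {
        sigma_noise <- estimate_noise_sd(z[max(1L, k - round(config$noise_window_s / dt)):k],
                                         config, prev = sigma_noise)
      }
      lo_r <- max(1L, k - n_resp_buf)
      if (k - lo_r > 20L) {
        sigma2_resp <- var(xr_t[lo_r:(k - 1L)])
      }
    }
    f_r <- f_r + a_iir * (raw_f - f_r)
    f_r <- min(max(f_r, config$f_min), config$f_max)
    w <- 2 * pi * f_r
    a21 <- -w^2 * dt
    q2 <- w^2
    q3 <- alpha * sigma2_resp
    R <- max(sigma_noise^2, 1e-12)

    # ---- predict: x- = A x, P- = A P A' + Q (hand-expanded 3x3)
    x1p <- x1 + dt * x2
    x2p <- a21 * x1 + x2
    x3p <- x3
    r11 <- p11 + dt * p12; r12 <- p12 + dt * p22; r13 <- p13 + dt * p23
    r21 <- a21 * p11 + p12; r22 <- a21 * p12 + p22; r23 <- a21 * p13 + p23
    pp11 <- r11 + dt * r12 + q0
    pp12 <- a21 * r11 + r12
    pp13 <- r13
    pp22 <- a21 * r21 + r22 + q2
    pp23 <- r23
    pp33 <- p33 + q3

    # ---- scalar update with H = [1, 0, 1], Joseph-form covariance
    S <- pp11 + 2 * pp13 + pp33 + R
    k1 <- (pp11 + pp13) / S
    k2 <- (pp12 + pp23) / S
    k3 <- (pp13 + pp33) / S
    nu <- z[k] - (x1p + x3p)
    x1 <- x1p + k1 * nu
    x2 <- x2p + k2 * nu
    x3 <- x3p + k3 * nu
    b11 <- 1 - k1
    m11 <- b11 * pp11 - k1 * pp13
    m12 <- b11 * pp12 - k1 * pp23
    m13 <- b11 * pp13 - k1 * pp33
    m21 <- pp12 - k2 * (pp11 + pp13)
    m22 <- pp22 - k2 * (pp12 + pp23)
    m23 <- pp23 - k2 * (pp13 + pp33)
    m31 <- (1 - k3) * pp13 - k3 * pp11
    m33 <- (1 - k3) * pp33 - k3 * pp13
    p11 <- m11 * b11 - m13 * k1 + R * k1 * k1
    p12 <- -k2 * (m11 + m13) + m12 + R * k1 * k2
    p13 <- -k3 * m11 + (1 - k3) * m13 + R * k1 * k3
    p22 <- -k2 * (m21 + m23) + m22 + R * k2 * k2
    p23 <- -k3 * m21 + (1 - k3) * m23 + R * k2 * k3
    p33 <- -k3 * m31 + (1 - k3) * m33 + R * k3 * k3

    # ---- multi-step prediction X_hat(k + h | k), closed-form A^h
    pr <- osc_predict(x1, x2, w, dt, hh)
    pred_xr[k, ] <- pr$xr

    xr_t[k] <- x1
    vr_t[k] <- x2
    c_t[k] <- x3
    fr_t[k] <- f_r
    nu_t[k] <- nu
    P_t[k, ] <- c(p11, p12, p13, p22, p23, p33)
  }

  trace <- tibble::tibble(
    time_s = measured$time_s,
    z_mm = z,
    xr_mm = xr_t,
    vr_mms = vr_t,
    c_mm = c_t,
    fr_hz = fr_t,
    innovation_mm = nu_t,
    pred_mm = pred_xr[, H_max] + c_t
  )
  structure(
    list(
      trace = trace, pred_xr = pred_xr, P = P_t, config = config,
      signal_meta = signal_meta(measured),
      state = list(x = c(x1, x2, x3),
                   P = matrix(c(p11, p12, p13, p12, p22, p23, p13, p23, p33), 3),
                   f_r = f_r, k = n)
    ),
    class = "resp_kf"
  )
}

#' @export
print.resp_kf <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<resp_kf> %d steps @ %.4g Hz | settled frequency %.3f Hz | innovation sd %.3f mm | horizon %d steps\n",
    g$n, 1 / x$config$dt, g$fr_hz, g$innovation_sd_mm, x$config$horizon_steps
  ))
  invisible(x)
}
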