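#' Simulate an ideal sinusoidal respiratory trace
#'
#' Benchmark waveform for steady resting respiration: a pure sine with 10 mm
#' amplitude and 5 s period by default. No jitter or noise is applied; corrupt
#' the output with [add_noise()], [apply_latency()] and [add_baseline_drift()]
#' to emulate a measurement chain.
#'
#' @param amplitude_mm Peak displacement \[mm\], > 0.
#' @param period_s Breathing period \[s\], > 0.
#' @param duration_s Signal length \[s\].
#' @param dt Sample interval \[s\].
#' @param t0 Start time \[s\].
#' @return A [resp_signal()] with `values[i] = A * sin(2 * pi * t_i / T)`.
#' @examples
#' s <- sim_sine(duration_s = 10)
#' max(s$displacement_mm)
#' @export
sim_sine <- function(amplitude_mm = 10, period_s = 5, duration_s = 60,
                     dt = 0.01, t0 = 0) {
  check_scalar(amplitude_mm, "amplitude_mm", positive = TRUE)
  check_scalar(period_s, "period_s", positive = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  n <- max(1L, round(duration_s / dt))
  tt <- t0 + dt * (0:(n - 1L))
  resp_signal(
    amplitude_mm * sin(2 * pi * tt / period_s),
    dt = dt, t0 = t0,
    meta = list(
      pattern = "sine", amplitude_mm = amplitude_mm, period_s = period_s
    )
  )
}

#' Simulate breathing waveforms (regular, shallow, irregular)
#'
#' Cycle-by-cycle construction: each breath is a raised-cosine bump
#' `A_j * (1 - cos(2 * pi * tau / T_j)) / 2` running valley-to-valley, with the
#' cycle amplitude `A_j` and period `T_j` drawn as `nominal * (1 + jitter * N(0,1))`
#' (clipped away from zero). The raised cosine gives the flat end-inspiration
#' plateau seen in relaxed breathing. `shallow` is the same construction at a
#' 3-5 mm nominal amplitude. `irregular` additionally superimposes
#' high-frequency random pulses (Poisson arrivals) and a slow linear amplitude
#' trend emulating non-stationary breathing.
#'
#' @param pattern `"regular"`, `"shallow"` or `"irregular"`.
#' @param amplitude_mm Nominal cycle amplitude \[mm\]. Defaults to 10 mm, or
#'   4 mm for `pattern = "shallow"`.
#' @param period_s Nominal cycle period \[s\].
#' @param duration_s Signal length \[s\]; must cover at least one cycle.
#' @param dt Sample interval \[s\].
#' @param amplitude_jitter_frac,period_jitter_frac Cycle-to-cycle fractional
#'   jitter (sd of the multiplicative Gaussian factor).
#' @param pulse_rate_per_min Poisson arrival rate of motion-artifact pulses
#'   (irregular pattern only).
#' @param pulse_amplitude_mm Pulse height \[mm\].
#' @param pulse_width_s Pulse full width \[s\] (raised-cosine bump, ~0.3 s).
#' @param trend_frac Fractional amplitude change from start to end of the
#'   signal (irregular pattern only); the sign is drawn from the seed.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A [resp_signal()]; injected pulse times are recorded in
#'   `signal_meta()$pulse_times_s`.
#' @examples
#' b <- sim_breathing("regular", duration_s = 30, seed = 1)
#' range(b$displacement_mm)
#' @export
sim_breathing <- function(pattern = c("regular", "shallow", "irregular"),
                          amplitude_mm = NULL, period_s = 5, duration_s = 120,
                          dt = 0.01,
                          amplitude_jitter_frac = 0.05,
                          period_jitter_frac = 0.05,
                          pulse_rate_per_min = 4,
                          pulse_amplitude_mm = 5,
                          pulse_width_s = 0.3,
                          trend_frac = 0.3,
                          seed = NULL) {
  pattern <- match.arg(pattern)
  if (is.null(amplitude_mm)) {
    amplitude_mm <- if (pattern == "shallow") 4 else 10
  }
  check_scalar(amplitude_mm, "amplitude_mm", positive = TRUE)
  check_scalar(period_s, "period_s", positive = TRUE)
  check_scalar(amplitude_jitter_frac, "amplitude_jitter_frac", nonneg = TRUE)
  check_scalar(period_jitter_frac, "period_jitter_frac", nonneg = TRUE)
  if (duration_s < period_s) {
    abort("`duration_s` must cover at least one breathing cycle.")
  }

  with_seed(seed, {
    # Draw cycles until they cover the requested duration.
    n_guess <- ceiling(duration_s / period_s * 2) + 8L
    amps <- periods <- numeric(0)
    while (sum(periods) < duration_s) {
      a <- amplitude_mm * (1 + amplitude_jitter_frac * rnorm(n_guess))
      p <- period_s * (1 + period_jitter_frac * rnorm(n_guess))
      amps <- c(amps, pmax(a, 0.05 * amplitude_mm))
      periods <- c(periods, pmax(p, 0.2 * period_s))
    }
    starts <- cumsum(c(0, periods))

    n <- round(duration_s / dt)
    tt <- dt * (0:(n - 1L))
    cyc <- findInterval(tt, starts, rightmost.closed = FALSE)
    tau <- tt - starts[cyc]
    vals <- amps[cyc] * (1 - cos(2 * pi * tau / periods[cyc])) / 2
    peak_times <- starts[seq_along(periods)] + periods / 2
    peak_times <- peak_times[peak_times < duration_s]

    pulse_times <- numeric(0)
    if (pattern == "irregular") {
      # Slow linear amplitude trend (non-stationarity).
      sgn <- if (runif(1) < 0.5) -1 else 1
      vals <- vals * (1 + sgn * trend_frac * tt / duration_s)
      # Poisson pulse artifacts: short raised-cosine bumps.
      n_pulses <- rpois(1, pulse_rate_per_min * duration_s / 60)
      if (n_pulses > 0) {
        pulse_times <- sort(runif(n_pulses, 0, duration_s))
        for (tp in pulse_times) {
          idx <- which(abs(tt - tp) <= pulse_width_s / 2)
          vals[idx] <- vals[idx] +
            pulse_amplitude_mm * (1 + cos(2 * pi * (tt[idx] - tp) / pulse_width_s)) / 2
        }
      }
    }

    resp_signal(
      vals, dt = dt,
      meta = list(
        pattern = pattern, amplitude_mm = amplitude_mm, period_s = period_s,
        seed = seed, peak_times_s = peak_times, pulse_times_s = pulse_times
      )
    )
  })
}

#' Corrupt a signal with additive Gaussian measurement noise
#'
#' @param signal A [resp_signal()].
#' @param noise_sd_mm Noise standard deviation \[mm\], >= 0.
#' @param seed Integer seed for reproducibility.
#' @return The signal with i.i.d. zero-mean Gaussian noise added per sample.
#' @export
add_noise <- function(signal, noise_sd_mm, seed = NULL) {
  check_scalar(noise_sd_mm, "noise_sd_mm", nonneg = TRUE)
  if (noise_sd_mm == 0) {
    return(signal)
  }
  with_seed(seed, {
    set_values(
      signal,
      signal$displacement_mm + rnorm(nrow(signal), sd = noise_sd_mm),
      extra_meta = list(noise_sd_mm = noise_sd_mm)
    )
  })
}

#' Delay a signal to emulate measurement / display latency
#'
#' The delayed stream lags the actual respiratory motion: `out[i] = in[i - k]`
#' with `k = round(latency_s / dt)`. The leading `k` samples hold the first
#' input value and length is preserved. Fractional latencies are rounded to
#' the nearest sample and the realized latency recorded in the meta.
#'
#' @param signal A [resp_signal()].
#' @param latency_s Latency \[s\], >= 0 and shorter than the signal.
#' @return The delayed signal; `signal_meta()$latency_s` holds the realized
#'   (rounded) latency.
#' @export
apply_latency <- function(signal, latency_s) {
  check_scalar(latency_s, "latency_s", nonneg = TRUE)
  dt <- signal_dt(signal)
  k <- round(latency_s / dt)
  if (k >= nrow(signal)) {
    abort("`latency_s` is longer than the signal.")
  }
  v <- signal$displacement_mm
  out <- if (k == 0) v else c(rep(v[1L], k), v[seq_len(length(v) - k)])
  set_values(signal, out, extra_meta = list(latency_s = k * dt))
}

#' Add a slow sinusoidal baseline drift
#'
#' Emulates the slowly varying baseline offset (posture shifts, platform
#' drift) that the filter's third state component absorbs. Warns when the
#' drift period is not much longer than the breathing period.
#'
#' @param signal A [resp_signal()].
#' @param drift_amplitude_mm Drift amplitude \[mm\] (0 allowed).
#' @param drift_period_s Drift period \[s\].
#' @return The signal with `drift_amplitude * sin(2 * pi * t / drift_period)`
#'   added to every sample.
#' @export
add_baseline_drift <- function(signal, drift_amplitude_mm, drift_period_s = 120) {
  check_scalar(drift_amplitude_mm, "drift_amplitude_mm", nonneg = TRUE)
  check_scalar(drift_period_s, "drift_period_s", positive = TRUE)
  if (drift_amplitude_mm == 0) {
    return(signal)
  }
  breath_period <- signal_meta(signal)$period_s
  if (!is.null(breath_period) && drift_period_s < 5 * breath_period) {
    warn("drift period is < 5x the breathing period; drift will not be slow relative to respiration.")
  }
  set_values(
    signal,
    signal$displacement_mm +
      drift_amplitude_mm * sin(2 * pi * signal$time_s / drift_period_s),
    extra_meta = list(
      drift_amplitude_mm = drift_amplitude_mm, drift_period_s = drift_period_s
    )
  )
}
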