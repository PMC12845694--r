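#' Gating configuration
#'
#' Parameters of anticipatory end-inspiration detection and template
#' validation.
#'
#' @param horizon_steps Anticipation horizon (filter steps ahead of the
#'   latency-compensated state in which a predicted velocity zero-crossing
#'   triggers a prompt); 14 steps = 140 ms at 100 Hz.
#' @param refractory_s Minimum separation between emitted events \[s\]
#'   (~ the shortest plausible half-cycle at 20 breaths/min).
#' @param template_cycles Number of recent cycles averaged into the breathing
#'   template.
#' @param similarity_threshold Minimum normalized cross-correlation between
#'   the current cycle prefix and the template prefix.
#' @param amplitude_band_frac Accepted cycle-amplitude band around the
#'   template mean (fractional, default +/-50%).
#' @param period_band_frac Accepted band around the template's mean
#'   valley-to-peak time for the elapsed cycle time (fractional,
#'   default +/-30%).
#' @param trend_window_steps Window over which the filtered displacement must
#'   be non-decreasing and close to its running cycle maximum.
#' @param template_len Fixed resampling length of the template cycle.
#' @param warmup_s Burn-in period \[s\] during which no prompts are emitted
#'   (default 10 s, about two nominal breathing cycles). From a cold start
#'   the respiratory and baseline components of the measurement are not
#'   separately observable until roughly a full cycle has been seen, and the
#'   breathing template needs two completed cycles, so early prompts carry no
#'   phase information; streaming evaluation starts after the burn-in.
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(horizon_steps = 14, refractory_s = 2.0,
                          template_cycles = 5, similarity_threshold = 0.8,
                          amplitude_band_frac = 0.5, period_band_frac = 0.3,
                          trend_window_steps = 10, template_len = 100,
                          warmup_s = 10) {
  check_scalar(refractory_s, "refractory_s", positive = TRUE)
  if (!(similarity_threshold > 0 && similarity_threshold <= 1)) {
    abort("`similarity_threshold` must be in (0, 1].")
  }
  structure(
    list(
      horizon_steps = as.integer(horizon_steps), refractory_s = refractory_s,
      template_cycles = as.integer(template_cycles),
      similarity_threshold = similarity_threshold,
      amplitude_band_frac = amplitude_band_frac,
      period_band_frac = period_band_frac,
      trend_window_steps = as.integer(trend_window_steps),
      template_len = as.integer(template_len),
      warmup_s = warmup_s
    ),
    class = "gating_config"
  )
}

# Steps until the predicted velocity zero-crossing (+ to -), from the
# harmonic closed form: with Xr = rho sin(psi), Vr = rho w cos(psi) the peak
# lies at psi = pi/2, i.e. h* = (pi/2 - psi) / theta steps ahead. NA where the
# state is not rising.
steps_to_peak <- function(xr, vr, w, dt) {
  psi <- atan2(w * xr, vr)
  h <- (pi / 2 - psi) / atan(w * dt)
  h[vr <= 0] <- NA_real_
  h
}

#' Detect candidate end-inspiration prompts
#'
#' A candidate fires at step `k` when (i) the predicted velocity crosses zero
#' from positive to negative within the horizon window (for finite-difference
#' traces without a frequency column, when the velocity itself crosses at
#' `k`), and (ii) the displacement has been non-decreasing over the last
#' `trend_window_steps` and sits within 10% of its running cycle maximum.
#' At most one candidate is kept per refractory period.
#'
#' @param trace A tibble with columns `time_s`, `xr_mm`, `vr_mms` and (for
#'   predictive detection) `fr_hz`, e.g. the trace of [run_filter()].
#' @param config A [gating_config()].
#' @param horizon_steps Total prediction window in steps; defaults to
#'   `config$horizon_steps`. [run_gating()] extends it by the measurement
#'   latency so prompts anticipate the true peak.
#' @param dt Sample interval \[s\]; inferred from `time_s` when missing.
#' @return Tibble of candidates: `step`, `time_s`, `h_star` (steps to the
#'   predicted peak), `t_peak_s` (predicted peak time on the measured-signal
#'   time base).
#' @export
detect_candidates <- function(trace, config = gating_config(),
                              horizon_steps = config$horizon_steps,
                              dt = NULL) {
  dt <- dt %||% median(diff(trace$time_s))
  xr <- trace$xr_mm
  vr <- trace$vr_mms
  n <- length(xr)
  if (n < 3L) {
    return(tibble::tibble(step = integer(0), time_s = numeric(0),
                          h_star = numeric(0), t_peak_s = numeric(0)))
  }

  if (!is.null(trace[["fr_hz"]])) {
    w <- 2 * pi * trace$fr_hz
    h_star <- steps_to_peak(xr, vr, w, dt)
    cand <- !is.na(h_star) & h_star <= horizon_steps
  } else {
    # instantaneous detection: velocity sign change + -> - at k
    cand <- c(FALSE, vr[-n] > 0 & vr[-1L] <= 0)
    h_star <- rep(0, n)
  }

  # (ii) upward-trend guard on the displacement; all scales are causal
  # running quantities so a truncated input reproduces its prefix exactly
  crng <- pmax(cummax(xr) - cummin(xr), 1e-9)
  wlen <- max(2L, config$trend_window_steps)
  ok_trend <- rep(TRUE, n)
  for (j in seq_len(wlen - 1L)) {
    lagged <- c(rep(NA_real_, j), xr[seq_len(n - j)])
    ok_trend <- ok_trend & !is.na(lagged) & (xr >= lagged - 0.01 * crng)
  }
  # running maximum within the current cycle (reset at velocity - -> +)
  valley <- c(FALSE, vr[-n] < 0 & vr[-1L] >= 0)
  cyc <- cumsum(valley) + 1L
  run_max <- unlist(lapply(split(xr, cyc), cummax), use.names = FALSE)
  near_max <- xr >= run_max - 0.1 * crng

  idx <- which(cand & ok_trend & near_max)
  idx <- idx[trace$time_s[idx] >= trace$time_s[1L] + (config$warmup_s %||% 0)]
  # refractory: keep the first candidate, drop followers within refractory_s
  keep <- integer(0)
  last_t <- -Inf
  for (i in idx) {
    if (trace$time_s[i] - last_t >= config$refractory_s) {
      keep <- c(keep, i)
      last_t <- trace$time_s[i]
    }
  }
  tibble::tibble(
    step = keep,
    time_s = trace$time_s[keep],
    h_star = h_star[keep],
    t_peak_s = trace$time_s[keep] + h_star[keep] * dt
  )
}

#' Learn a personalized breathing template
#'
#' Averages recent valley-to-valley cycles into a fixed-length,
#' amplitude-normalized reference shape, recording the mean cycle amplitude,
#' period and valley-to-peak time. The template adapts online: it is
#' recomputed after each completed cycle from the last `template_cycles`
#' cycles.
#'
#' @param cycles List of numeric vectors (or [resp_signal()]s), one complete
#'   valley-to-valley cycle each.
#' @param config A [gating_config()].
#' @param dt Sample interval \[s\] of the cycles.
#' @return A list of class `resp_template`: `shape` (length
#'   `config$template_len`, normalized to \[0, 1\]), `mean_amplitude_mm`,
#'   `mean_period_s`, `mean_ttp_s` (valley-to-peak time), `n_cycles`,
#'   `ready` (FALSE with fewer than 2 cycles).
#' @export
learn_template <- function(cycles, config = gating_config(), dt = 0.01) {
  cycles <- lapply(cycles, function(cc) {
    if (is.data.frame(cc)) cc$displacement_mm else as.numeric(cc)
  })
  cycles <- cycles[lengths(cycles) >= 4L]
  n_c <- length(cycles)
  if (n_c < 2L) {
    return(structure(
      list(shape = rep(NA_real_, config$template_len),
           mean_amplitude_mm = NA_real_, mean_period_s = NA_real_,
           mean_ttp_s = NA_real_, n_cycles = n_c, ready = FALSE),
      class = "resp_template"
    ))
  }
  cycles <- tail(cycles, config$template_cycles)
  L <- config$template_len
  norm_one <- function(v) {
    rng <- range(v)
    u <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else rep(0, length(v))
    approx(seq(0, 1, length.out = length(u)), u,
           xout = seq(0, 1, length.out = L))$y
  }
  shapes <- vapply(cycles, norm_one, numeric(L))
  structure(
    list(
      shape = rowMeans(shapes),
      mean_amplitude_mm = mean(vapply(cycles, function(v) diff(range(v)), numeric(1))),
      mean_period_s = mean(lengths(cycles)) * dt,
      mean_ttp_s = mean(vapply(cycles, which.max, numeric(1))) * dt,
      n_cycles = length(cycles), ready = TRUE
    ),
    class = "resp_template"
  )
}

#' Validate a candidate prompt against the learned template
#'
#' Dual validation: the candidate (already accepted by the primary
#' zero-crossing rule) is confirmed only when the current cycle is consistent
#' with the learned breathing template: (a) normalized cross-correlation of
#' the amplitude-normalized cycle prefix with the template prefix is at least
#' `similarity_threshold`, (b) the cycle amplitude so far lies within
#' `mean * (1 +/- amplitude_band_frac)`, and (c) the elapsed time since the
#' cycle-start valley lies within `mean_ttp * (1 +/- period_band_frac)`.
#' With an unready template the primary rule alone decides (flagged).
#'
#' @param candidate One-row tibble from [detect_candidates()] (unused fields
#'   tolerated; may be NULL).
#' @param template A [learn_template()] result.
#' @param current_cycle Numeric vector (or [resp_signal()]): samples from the
#'   cycle-start valley up to the candidate step.
#' @param config A [gating_config()].
#' @param dt Sample interval \[s\].
#' @return List: `valid`, `score` (similarity), `template_ready`, `reason`.
#' @export
validate_event <- function(candidate, template, current_cycle,
                           config = gating_config(), dt = 0.01) {
  v <- if (is.data.frame(current_cycle)) current_cycle$displacement_mm else as.numeric(current_cycle)
  if (!isTRUE(template$ready)) {
    return(list(valid = TRUE, score = NA_real_, template_ready = FALSE,
                reason = "template_not_ready"))
  }
  elapsed <- length(v) * dt
  amp <- diff(range(v))

  band <- config$amplitude_band_frac
  if (amp < template$mean_amplitude_mm * (1 - band) ||
      amp > template$mean_amplitude_mm * (1 + band)) {
    return(list(valid = FALSE, score = NA_real_, template_ready = TRUE,
                reason = "amplitude_band"))
  }
  pband <- config$period_band_frac
  if (elapsed < template$mean_ttp_s * (1 - pband) ||
      elapsed > template$mean_ttp_s * (1 + pband)) {
    return(list(valid = FALSE, score = NA_real_, template_ready = TRUE,
                reason = "period_band"))
  }

  # similarity of the normalized prefix with the template prefix
  L <- config$template_len
  m <- max(5L, min(L, round(L * elapsed / template$mean_period_s)))
  rng <- range(v)
  u <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else rep(0, length(v))
  pre <- approx(seq(0, 1, length.out = length(u)), u,
                xout = seq(0, 1, length.out = m))$y
  tpl <- template$shape[seq_len(m)]
  score <- sum(pre * tpl) / sqrt(sum(pre^2) * sum(tpl^2))
  if (!is.finite(score) || score < config$similarity_threshold) {
    return(list(valid = FALSE, score = score, template_ready = TRUE,
                reason = "similarity"))
  }
  list(valid = TRUE, score = score, template_ready = TRUE, reason = "ok")
}

# Causal 5-sample moving-average smoothing + backward-difference velocity
# over a 10-sample baseline: the instantaneous (Mode A) detector. The causal
# window adds a fixed ~70 ms detector lag on top of the measurement latency.
fd_velocity <- function(z, dt, diff_steps = 10L) {
  n <- length(z)
  sm <- as.numeric(stats::filter(z, rep(1 / 5, 5), sides = 1))
  sm[is.na(sm)] <- cumsum(z)[is.na(sm)] / seq_len(sum(is.na(sm)))
  v <- numeric(n)
  if (n > diff_steps) {
    idx <- (diff_steps + 1L):n
    v[idx] <- (sm[idx] - sm[idx - diff_steps]) / (diff_steps * dt)
  }
  list(x = sm, v = v)
}

# Causal valley detection for cycle segmentation: a velocity - -> + crossing
# counts as a cycle-start valley only while the displacement sits in the low
# part of its (causal) running range; crossings within 1 s of an accepted
# valley are dropped. This rejects the velocity wiggles that occur around the
# flat end-inspiration plateau.
segment_valleys <- function(xr, vr, dt, min_sep_s = 1) {
  n <- length(xr)
  if (n < 3L) {
    return(integer(0))
  }
  crossing <- c(FALSE, vr[-n] < 0 & vr[-1L] >= 0)
  cmean <- cumsum(xr) / seq_len(n)
  crng <- cummax(xr) - cummin(xr)
  low <- xr < cmean - 0.15 * crng
  idx <- which(crossing & low)
  keep <- integer(0)
  last <- -Inf
  min_sep <- min_sep_s / dt
  for (i in idx) {
    if (i - last >= min_sep) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}

#' Run end-inspiration gating over a measured signal
#'
#' Mode B (predictive): runs the adaptive Kalman filter and prompts when the
#' predicted velocity zero-crossing falls within
#' `round(latency_s / dt) + horizon_steps` steps, so the prompt anticipates
#' the true end-inspiration despite the measurement/display latency. Mode A
#' (baseline): instantaneous detection of the velocity zero-crossing on the
#' (delayed) measurement via smoothed finite differences, so prompts trail
#' the true peak by roughly the latency. In both modes candidates pass the
#' template dual validation before being emitted; rejected candidates are
#' suppressed and logged in the `candidates` attribute.
#'
#' @param measured A [resp_signal()] measurement stream (typically corrupted
#'   with [add_noise()] and [apply_latency()]).
#' @param mode `"B"` (Kalman-predictive) or `"A"` (baseline).
#' @param fconfig A [kf_config()].
#' @param gconfig A [gating_config()].
#' @param latency_s Measurement/display latency \[s\]; defaults to the value
#'   recorded by [apply_latency()] in the signal meta (0 when absent).
#' @return A tibble of class `resp_gating` with one row per emitted event:
#'   `t_prompt_s`, `t_predicted_peak_s` (estimated true-frame peak time),
#'   `validated`, `score`, `template_ready`, `mode`. Attributes: `candidates`
#'   (all candidates with validation outcome), `mode`, `latency_s`, `fit`
#'   (the `resp_kf` fit for mode B).
#' @examples
#' ev <- sim_sine(duration_s = 40) |>
#'   add_noise(0.3, seed = 2) |>
#'   apply_latency(0.2) |>
#'   run_gating(mode = "B")
#' nrow(ev)
#' @export
run_gating <- function(measured, mode = c("B", "A"), fconfig = kf_config(),
                       gconfig = gating_config(), latency_s = NULL) {
  mode <- match.arg(mode)
  dt <- signal_dt(measured)
  latency_s <- latency_s %||% signal_meta(measured)$latency_s %||% 0
  lat_steps <- round(latency_s / dt)

  fit <- NULL
  if (mode == "B") {
    fconfig$dt <- dt
    fit <- run_filter(measured, fconfig)
    trace <- fit$trace
    H_total <- lat_steps + gconfig$horizon_steps
  } else {
    fd <- fd_velocity(measured$displacement_mm, dt)
    trace <- tibble::tibble(time_s = measured$time_s, xr_mm = fd$x,
                            vr_mms = fd$v)
    H_total <- 0L
  }

  cands <- detect_candidates(trace, gconfig, horizon_steps = H_total, dt = dt)

  # online valley-to-valley segmentation of the (filtered or smoothed) signal
  valley_idx <- segment_valleys(trace$xr_mm, trace$vr_mms, dt)

  events <- vector("list", nrow(cands))
  cand_log <- cands
  cand_log$valid <- logical(nrow(cands))
  cand_log$score <- NA_real_
  cand_log$template_ready <- logical(nrow(cands))
  cand_log$reason <- character(nrow(cands))

  for (i in seq_len(nrow(cands))) {
    k <- cands$step[i]
    past_valleys <- valley_idx[valley_idx <= k]
    # boundaries of the most recent completed cycles available at step k
    done <- tail(past_valleys, gconfig$template_cycles + 1L)
    if (length(done) >= 2L) {
      cyc_list <- lapply(seq_len(length(done) - 1L), function(j) {
        trace$xr_mm[done[j]:done[j + 1L]]
      })
    } else {
      cyc_list <- list()
    }
    tpl <- learn_template(cyc_list, gconfig, dt = dt)
    cur_start <- if (length(past_valleys)) max(past_valleys) else 1L
    val <- validate_event(cands[i, ], tpl, trace$xr_mm[cur_start:k],
                          gconfig, dt = dt)
    cand_log$valid[i] <- val$valid
    cand_log$score[i] <- val$score
    cand_log$template_ready[i] <- val$template_ready
    cand_log$reason[i] <- val$reason
    if (val$valid) {
      t_prompt <- cands$time_s[i]
      t_peak <- cands$t_peak_s[i] - (if (mode == "B") latency_s else 0)
      if (mode == "B") t_peak <- max(t_peak, t_prompt)
      events[[i]] <- tibble::tibble(
        t_prompt_s = t_prompt,
        t_predicted_peak_s = t_peak,
        validated = TRUE,
        score = val$score,
        template_ready = val$template_ready,
        mode = mode
      )
    }
  }
  out <- dplyr::bind_rows(events)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      t_prompt_s = numeric(0), t_predicted_peak_s = numeric(0),
      validated = logical(0), score = numeric(0),
      template_ready = logical(0), mode = character(0)
    )
  }
  structure(
    out,
    candidates = cand_log, mode = mode, latency_s = latency_s, fit = fit,
    class = c("resp_gating", class(tibble::tibble()))
  )
}
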