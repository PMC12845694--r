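#' Target-point error series
#'
#' `TPE(t) = || P_true(t) - P_displayed(t) ||_2` per sample: the instantaneous
#' Euclidean distance between the true target position and the position the
#' navigation display shows.
#'
#' @param true_traj,displayed_traj Tibbles/data frames with columns `time_s`,
#'   `x_mm`, `y_mm`, `z_mm` (or N x 3 matrices), equal length and time-aligned.
#' @return Tibble with `time_s` (when available) and `tpe_mm`.
#' @export
target_point_error_series <- function(true_traj, displayed_traj) {
  coords <- function(d) {
    if (is.matrix(d)) d else as.matrix(d[, c("x_mm", "y_mm", "z_mm")])
  }
  A <- coords(true_traj)
  B <- coords(displayed_traj)
  if (nrow(A) != nrow(B)) {
    abort(sprintf("trajectory length mismatch: %d vs %d samples.", nrow(A), nrow(B)))
  }
  tibble::tibble(
    time_s = if (!is.matrix(true_traj) && "time_s" %in% names(true_traj)) {
      true_traj$time_s
    } else {
      NA_real_
    },
    tpe_mm = sqrt(rowSums((A - B)^2))
  )
}

#' Summary statistics of an error series
#'
#' Arithmetic mean, population standard deviation and RMSE; by the population
#' convention `RMSE^2 = mean^2 + sd^2` holds exactly.
#'
#' @param series Numeric vector (or tibble with `tpe_mm`).
#' @return One-row tibble: `mean`, `sd`, `rmse`, `max`, `n`.
#' @examples
#' summarize_errors(c(0, 3, 4))
#' @export
summarize_errors <- function(series) {
  x <- if (is.data.frame(series)) series$tpe_mm else as.numeric(series)
  if (!length(x)) {
    abort("empty error series.")
  }
  tibble::tibble(
    mean = mean(x), sd = pop_sd(x), rmse = sqrt(mean(x^2)),
    max = max(x), n = length(x)
  )
}

#' Annotate gold-standard end-inspiration times
#'
#' Per-cycle displacement maxima of the uncorrupted ground-truth signal,
#' detected with the shared prominence-filtered extremum detector and refined
#' to sub-sample precision by parabolic interpolation. Deterministic.
#'
#' @param true_signal A [resp_signal()] (simulator ground truth).
#' @return Numeric vector of peak times `T_gold` \[s\]; empty for flat or
#'   sub-cycle signals.
#' @examples
#' annotate_gold(sim_sine(duration_s = 20))
#' @export
annotate_gold <- function(true_signal) {
  ext <- detect_extrema(true_signal, refine = TRUE)
  ext$time_s[ext$type == "peak"]
}

#' Prompt accuracy and timing statistics
#'
#' Matches prompts to gold end-inspiration times one-to-one (nearest pairs
#' first; each prompt consumes at most one gold peak and vice versa) and
#' scores `Delta_T = T_prompt - T_gold`. Accuracy is the percentage of gold
#' peaks with a matched prompt inside the tolerance window; `Delta_T`
#' statistics are reported in milliseconds over matched prompts (cycles with
#' no prompt count as misses for accuracy and are excluded from `Delta_T`).
#' Negative `Delta_T` means the prompt anticipated the true peak.
#'
#' @param events A [run_gating()] result (or tibble with `t_prompt_s`).
#' @param gold Numeric vector of gold peak times \[s\] ([annotate_gold()]).
#' @param tolerance_s Half-width of the tolerance window centred on each gold
#'   peak \[s\] (default 0.3 s).
#' @param max_match_s Maximum |Delta_T| for a prompt to be considered a match
#'   at all; defaults to half the median gold inter-peak interval, so a
#'   prompt can never be attributed to a different breathing cycle. Gold
#'   peaks without a prompt inside this radius are misses and contribute no
#'   `Delta_T`.
#' @return One-row tibble: `accuracy_pct`, `dt_mean_ms`, `dt_sd_ms`,
#'   `n_gold`, `n_prompts`, `n_matched`, `n_hit`.
#' @export
prompt_metrics <- function(events, gold, tolerance_s = 0.3,
                           max_match_s = NULL) {
  if (!length(gold)) {
    abort("`gold` must contain at least one end-inspiration time.")
  }
  prompts <- if (is.data.frame(events)) events$t_prompt_s else as.numeric(events)
  n_gold <- length(gold)
  if (!length(prompts)) {
    return(tibble::tibble(
      accuracy_pct = 0, dt_mean_ms = NA_real_, dt_sd_ms = NA_real_,
      n_gold = n_gold, n_prompts = 0L, n_matched = 0L, n_hit = 0L
    ))
  }
  max_match_s <- max_match_s %||% if (n_gold > 1L) {
    median(diff(sort(gold))) / 2
  } else {
    Inf
  }
  # injective nearest-neighbour matching, closest pairs first
  D <- abs(outer(gold, prompts, "-"))
  D[D > max_match_s] <- Inf
  match_p <- rep(NA_integer_, n_gold)
  ord <- order(D)
  used_g <- logical(n_gold)
  used_p <- logical(length(prompts))
  for (ij in ord) {
    if (is.infinite(D[ij])) break
    i <- (ij - 1L) %% n_gold + 1L
    j <- (ij - 1L) %/% n_gold + 1L
    if (!used_g[i] && !used_p[j]) {
      match_p[i] <- j
      used_g[i] <- TRUE
      used_p[j] <- TRUE
    }
    if (all(used_g) || all(used_p)) break
  }
  matched <- which(!is.na(match_p))
  dts <- prompts[match_p[matched]] - gold[matched]
  hits <- sum(abs(dts) <= tolerance_s)
  tibble::tibble(
    accuracy_pct = 100 * hits / n_gold,
    dt_mean_ms = 1000 * mean(dts),
    dt_sd_ms = 1000 * pop_sd(dts),
    n_gold = n_gold,
    n_prompts = length(prompts),
    n_matched = length(matched),
    n_hit = hits
  )
}

# Map a 1-D displacement signal to a 3-D trajectory along a unit motion axis
# (default superior-inferior) so the target-point error applies verbatim.
signal_to_traj <- function(signal, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  tibble::tibble(
    time_s = signal$time_s,
    x_mm = signal$displacement_mm * axis[1L],
    y_mm = signal$displacement_mm * axis[2L],
    z_mm = signal$displacement_mm * axis[3L]
  )
}

#' Compare uncompensated and Kalman-compensated navigation
#'
#' Runs the full simulated verification protocol on one ground-truth signal:
#' corrupts it with measurement noise and latency, then evaluates two display
#' modes against the truth on the same seeded measurement stream.
#' Mode A (baseline): the displayed position is the raw delayed measurement
#' and prompts come from instantaneous end-inspiration detection. Mode B: the
#' displayed position is the filter's latency-compensated prediction
#' (`h = round(latency_s / dt)` steps ahead) and prompts anticipate the peak
#' via the predictive gating rule. Both modes share the gold annotation and
#' tolerance window.
#'
#' @param true_signal A [resp_signal()] ground truth (no corruption).
#' @param noise_sd_mm Measurement noise sd \[mm\].
#' @param latency_s Measurement/display latency \[s\].
#' @param seed Seed for the shared noise draw.
#' @param fconfig A [kf_config()].
#' @param gconfig A [gating_config()].
#' @param tolerance_s Prompt tolerance window half-width \[s\].
#' @param axis Unit motion axis mapping the 1-D displacement into 3-D.
#' @return A list of class `resp_eval`: `report` (two-row tibble with TPE and
#'   prompt statistics per mode), `tpe` (per-sample TPE series, long format),
#'   `events_a`, `events_b`, `gold`, and the corruption parameters.
#' @examples
#' ev <- compare_modes(sim_sine(duration_s = 40), seed = 1)
#' ev$report
#' @export
compare_modes <- function(true_signal, noise_sd_mm = 0.3, latency_s = 0.2,
                          seed = NULL, fconfig = kf_config(),
                          gconfig = gating_config(), tolerance_s = 0.3,
                          axis = c(0, 0, 1)) {
  dt <- signal_dt(true_signal)
  lat_steps <- round(latency_s / dt)
  measured <- true_signal |>
    add_noise(noise_sd_mm, seed = derive_seed(seed, "noise")) |>
    apply_latency(latency_s)

  gold <- annotate_gold(true_signal)
  gold_eval <- gold[gold >= true_signal$time_s[1L] + (gconfig$warmup_s %||% 0)]
  if (!length(gold_eval)) {
    gold_eval <- gold
  }
  true_traj <- signal_to_traj(true_signal, axis)

  # Mode A: displayed = raw delayed measurement
  disp_a <- signal_to_traj(measured, axis)
  tpe_a <- target_point_error_series(true_traj, disp_a)
  ev_a <- run_gating(measured, mode = "A", fconfig = fconfig,
                     gconfig = gconfig, latency_s = latency_s)

  # Mode B: displayed = latency-compensated prediction
  fconfig$dt <- dt
  fconfig$horizon_steps <- max(fconfig$horizon_steps, lat_steps)
  ev_b <- run_gating(measured, mode = "B", fconfig = fconfig,
                     gconfig = gconfig, latency_s = latency_s)
  fit <- attr(ev_b, "fit")
  pred <- if (lat_steps >= 1L) {
    fit$pred_xr[, lat_steps] + fit$trace$c_mm
  } else {
    fit$trace$xr_mm + fit$trace$c_mm
  }
  disp_b <- signal_to_traj(set_values(measured, pred), axis)
  tpe_b <- target_point_error_series(true_traj, disp_b)

  pm_a <- prompt_metrics(ev_a, gold_eval, tolerance_s)
  pm_b <- prompt_metrics(ev_b, gold_eval, tolerance_s)
  report <- dplyr::bind_cols(
    tibble::tibble(mode = c("A", "B")),
    dplyr::bind_rows(
      dplyr::rename_with(summarize_errors(tpe_a), ~ paste0("tpe_", .x)),
      dplyr::rename_with(summarize_errors(tpe_b), ~ paste0("tpe_", .x))
    ),
    dplyr::bind_rows(pm_a, pm_b)
  )
  structure(
    list(
      report = report,
      tpe = dplyr::bind_rows(
        dplyr::mutate(tpe_a, mode = "A"),
        dplyr::mutate(tpe_b, mode = "B")
      ),
      events_a = ev_a, events_b = ev_b, gold = gold_eval,
      noise_sd_mm = noise_sd_mm, latency_s = latency_s, seed = seed,
      tolerance_s = tolerance_s
    ),
    class = "resp_eval"
  )
}

#' @export
print.resp_eval <- function(x, ...) {
  cat(sprintf("<resp_eval> noise %.3g mm, latency %.3g s, tolerance +/-%.3g s\n",
              x$noise_sd_mm, x$latency_s, x$tolerance_s))
  print(x$report)
  invisible(x)
}
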