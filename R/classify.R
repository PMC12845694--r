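#' Mean absolute amplitude of a respiratory signal
#'
#' `Ma = mean(|S(t_i)|)`, characterising overall breathing depth. Computed
#' literally on the raw samples; set `detrend = TRUE` to subtract the signal
#' mean first (a DC offset otherwise inflates Ma).
#'
#' @param signal A [resp_signal()].
#' @param detrend Subtract the signal mean before taking absolute values.
#' @return Mean absolute amplitude \[mm\].
#' @export
mean_amplitude <- function(signal, detrend = FALSE) {
  v <- signal$displacement_mm
  if (detrend) {
    v <- v - mean(v)
  }
  mean(abs(v))
}

#' Amplitude irregularity index
#'
#' `Ia = (sd(peak values) + sd(valley values)) / 2`: the average of the
#' standard deviations of detected peak and valley displacement values.
#' Population sd by convention (switchable).
#'
#' @param peaks,valleys Numeric vectors of extremum displacement values
#'   \[mm\], or a tibble from [detect_extrema()] passed as `peaks`.
#' @param population Use the population (divisor n) standard deviation.
#' @return Ia \[mm\]; 0 with a warning when fewer than 2 peaks or 2 valleys.
#' @examples
#' amplitude_irregularity(c(10, 12), c(-10, -12)) # 1
#' @export
amplitude_irregularity <- function(peaks, valleys = NULL, population = TRUE) {
  if (is.data.frame(peaks)) {
    ext <- peaks
    valleys <- ext$value_mm[ext$type == "valley"]
    peaks <- ext$value_mm[ext$type == "peak"]
  }
  if (length(peaks) < 2L || length(valleys) < 2L) {
    warn("fewer than 2 peaks or valleys; Ia set to 0.")
    return(0)
  }
  s <- if (population) pop_sd else sd
  (s(peaks) + s(valleys)) / 2
}

#' Phase irregularity index
#'
#' `Ip = (sd(peak-to-peak intervals) + sd(valley-to-valley intervals)) / 2`:
#' variability of the breathing rhythm, from the durations of consecutive
#' same-type extremum intervals. Population sd by convention.
#'
#' @param peak_times,valley_times Numeric vectors of extremum times \[s\], or
#'   a tibble from [detect_extrema()] passed as `peak_times`.
#' @param population Use the population standard deviation.
#' @return Ip \[s\]; 0 with a warning when fewer than 2 intervals of either
#'   type.
#' @examples
#' phase_irregularity(c(0, 4, 10), c(2, 7, 12)) # (sd{4,6} + sd{5,5})/2 = 0.5
#' @export
phase_irregularity <- function(peak_times, valley_times = NULL, population = TRUE) {
  if (is.data.frame(peak_times)) {
    ext <- peak_times
    valley_times <- ext$time_s[ext$type == "valley"]
    peak_times <- ext$time_s[ext$type == "peak"]
  }
  tp <- diff(sort(peak_times))
  tv <- diff(sort(valley_times))
  if (length(tp) < 2L || length(tv) < 2L) {
    warn("fewer than 2 intervals of either type; Ip set to 0.")
    return(0)
  }
  s <- if (population) pop_sd else sd
  (s(tp) + s(tv)) / 2
}

#' Breathing-pattern features of one or more signals
#'
#' Computes the three classification indices per signal: mean amplitude `Ma`,
#' amplitude irregularity `Ia` and phase irregularity `Ip`, from
#' prominence-filtered extrema ([detect_extrema()]).
#'
#' @param signals A [resp_signal()] or a (named) list of them.
#' @param ... Passed to [detect_extrema()].
#' @return A tibble with one row per signal: `signal_id`, `Ma_mm`, `Ia_mm`,
#'   `Ip_s`, `n_peaks`, `n_valleys`.
#' @export
breath_features <- function(signals, ...) {
  if (is.data.frame(signals)) {
    signals <- list(signals)
  }
  ids <- names(signals) %||% paste0("signal_", seq_along(signals))
  ids[ids == ""] <- paste0("signal_", which(ids == ""))
  purrr::map2_dfr(signals, ids, function(s, id) {
    ext <- detect_extrema(s, ...)
    pk <- ext[ext$type == "peak", ]
    vl <- ext[ext$type == "valley", ]
    tibble::tibble(
      signal_id = id,
      Ma_mm = mean_amplitude(s),
      Ia_mm = suppressWarnings(amplitude_irregularity(pk$value_mm, vl$value_mm)),
      Ip_s = suppressWarnings(phase_irregularity(pk$time_s, vl$time_s)),
      n_peaks = nrow(pk),
      n_valleys = nrow(vl)
    )
  })
}

#' Derive classification thresholds from a feature sample
#'
#' Thresholds follow the median-and-quartile rule: the medians of `Ia` and
#' `Ip` over the sample set, and the 25th percentile of `Ma` (linear
#' interpolation between order statistics, i.e. `quantile(type = 7)`).
#'
#' @param features Tibble from [breath_features()] with at least 3 rows.
#' @return A list of class `class_thresholds`: `ia_median`, `ip_median`,
#'   `ma_q25`.
#' @export
derive_thresholds <- function(features) {
  if (nrow(features) < 3L) {
    abort("need at least 3 feature rows to derive thresholds.")
  }
  structure(
    list(
      ia_median = median(features$Ia_mm),
      ip_median = median(features$Ip_s),
      ma_q25 = unname(quantile(features$Ma_mm, 0.25, type = 7))
    ),
    class = "class_thresholds"
  )
}

#' Classify breathing patterns
#'
#' Rule order: a signal for which either irregularity index strictly exceeds
#' its median threshold is `irregular`; otherwise it is `shallow` when its
#' mean amplitude falls within the lowest quartile (`Ma <= ma_q25`), else
#' `regular`.
#'
#' @param features Tibble from [breath_features()].
#' @param thresholds A [derive_thresholds()] result; derived from `features`
#'   when omitted.
#' @return `features` with a `label` column appended.
#' @examples
#' sigs <- list(
#'   regular = sim_sine(10, 5, 60),
#'   shallow = sim_sine(4, 5, 60),
#'   irregular = sim_breathing("irregular", duration_s = 60, seed = 3)
#' )
#' classify_breathing(breath_features(sigs))
#' @export
classify_breathing <- function(features, thresholds = NULL) {
  thresholds <- thresholds %||% derive_thresholds(features)
  dplyr::mutate(
    features,
    label = dplyr::case_when(
      .data$Ia_mm > thresholds$ia_median | .data$Ip_s > thresholds$ip_median ~ "irregular",
      .data$Ma_mm <= thresholds$ma_q25 ~ "shallow",
      TRUE ~ "regular"
    )
  )
}
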