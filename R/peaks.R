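# Prominence-filtered local-extremum detection. One implementation is shared
# by the frequency estimator, the breathing classifier and gold-standard
# end-inspiration annotation so that all modules agree on what counts as a
# breath.

# Indices of local maxima of `v` with topographic prominence >= min_prom and
# pairwise separation >= min_sep samples (greedy, highest first).
find_peak_idx <- function(v, min_sep = 1L, min_prom = 0) {
  n <- length(v)
  if (n < 3L) {
    return(integer(0))
  }
  d <- diff(v)
  # strict rise on the left, non-rise on the right; skips plateau duplicates
  cand <- which(d[-(n - 1L)] > 0 & d[-1L] <= 0) + 1L
  if (!length(cand)) {
    return(integer(0))
  }

  if (min_prom > 0) {
    # necessary condition (prominence <= v[i] - global min) prunes cheaply
    cand <- cand[v[cand] >= min(v) + min_prom]
    if (!length(cand)) {
      return(integer(0))
    }
    prom <- vapply(cand, function(i) {
      higher_l <- which(v[seq_len(i - 1L)] > v[i])
      lo_l <- min(v[(if (length(higher_l)) max(higher_l) else 1L):i])
      higher_r <- which(v[(i + 1L):n] > v[i]) + i
      lo_r <- min(v[i:(if (length(higher_r)) min(higher_r) else n)])
      v[i] - max(lo_l, lo_r)
    }, numeric(1))
    cand <- cand[prom >= min_prom]
    if (!length(cand)) {
      return(integer(0))
    }
  }

  # enforce minimum separation, keeping the taller peak
  keep <- logical(length(cand))
  for (j in order(v[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[j]) < min_sep)) {
      keep[j] <- TRUE
    }
  }
  sort(cand[keep])
}

# Sub-sample extremum time by parabolic interpolation through the three
# samples around index i. Returns the fractional-index offset in (-0.5, 0.5).
parabolic_offset <- function(v, i) {
  if (i <= 1L || i >= length(v)) {
    return(0)
  }
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (abs(denom) < 1e-12) {
    return(0)
  }
  off <- 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  max(min(off, 0.5), -0.5)
}

#' Detect respiratory peaks and valleys
#'
#' Local extrema filtered by topographic prominence (at least
#' `min_prominence_frac` of the global peak-to-peak range) and a minimum
#' separation of `min_sep_s` seconds, then reduced to a strictly alternating
#' peak/valley sequence (where two same-type extrema are adjacent the more
#' extreme one is kept).
#'
#' @param signal A [resp_signal()].
#' @param min_prominence_frac Prominence threshold as a fraction of the global
#'   peak-to-peak range (default 0.2).
#' @param min_sep_s Minimum separation between same-type extrema \[s\].
#' @param refine Logical; parabolic sub-sample refinement of extremum times.
#' @return A tibble with columns `time_s`, `value_mm`, `type`
#'   (`"peak"`/`"valley"`), ordered in time. Flat signals give zero rows.
#' @examples
#' detect_extrema(sim_sine(duration_s = 25))
#' @export
detect_extrema <- function(signal, min_prominence_frac = 0.2, min_sep_s = 1,
                           refine = FALSE) {
  v <- signal$displacement_mm
  tt <- signal$time_s
  dt <- signal_dt(signal)
  p2p <- diff(range(v))
  if (p2p <= .Machine$double.eps) {
    return(tibble::tibble(
      time_s = numeric(0), value_mm = numeric(0), type = character(0)
    ))
  }
  min_sep <- max(1L, round(min_sep_s / dt))
  min_prom <- min_prominence_frac * p2p
  pk <- find_peak_idx(v, min_sep, min_prom)
  vl <- find_peak_idx(-v, min_sep, min_prom)

  ext_time <- function(i, vec) {
    tt[i] + if (refine) parabolic_offset(vec, i) * dt else 0
  }
  out <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(
      idx = pk, time_s = vapply(pk, ext_time, numeric(1), vec = v),
      value_mm = v[pk], type = "peak"
    ),
    tibble::tibble(
      idx = vl, time_s = vapply(vl, ext_time, numeric(1), vec = -v),
      value_mm = v[vl], type = "valley"
    )
  ), .data$idx)

  # enforce alternation: within a run of equal types keep the extreme one
  if (nrow(out) > 1L) {
    run <- cumsum(c(TRUE, out$type[-1L] != out$type[-nrow(out)]))
    pick <- vapply(split(seq_len(nrow(out)), run), function(ix) {
      if (out$type[ix[1L]] == "peak") {
        ix[which.max(out$value_mm[ix])]
      } else {
        ix[which.min(out$value_mm[ix])]
      }
    }, integer(1))
    out <- out[sort(pick), ]
  }
  dplyr::select(out, "time_s", "value_mm", "type")
}
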