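# CSV / JSON interchange. The signal CSV dialect is fixed (comma, '.'
# decimal, LF, UTF-8) regardless of locale: header `time_s,displacement_mm`,
# one row per sample, meta serialized as leading `#key=value` comment lines.

#' Write a respiratory signal to CSV
#'
#' Deterministic formatting (6 decimal places); scalar and short-vector meta
#' entries are written as `#key=value` comment lines before the header, so a
#' written file can be read back with [read_signal_csv()] including its meta.
#'
#' @param signal A [resp_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  meta <- signal_meta(signal)
  meta <- meta[vapply(meta, function(m) {
    (is.numeric(m) || is.character(m) || is.logical(m)) && length(m) >= 1L && length(m) <= 50L
  }, logical(1))]
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    v <- if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
    sprintf("#%s=%s", k, paste(v, collapse = ";"))
  }, character(1))
  body <- sprintf("%.6f,%.6f", signal$time_s, signal$displacement_mm)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, "time_s,displacement_mm", body), con, sep = "\n")
  invisible(path)
}

#' Read a respiratory signal from CSV
#'
#' Expects the dialect written by [write_signal_csv()]: optional `#key=value`
#' comment lines, a `time_s,displacement_mm` header and a uniformly sampled,
#' monotone time column (uniformity tolerance 1e-6 s). Comment lines are
#' parsed back into the signal meta.
#'
#' @param path Input path.
#' @return A [resp_signal()].
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- list()
  for (ln in lines[seq_len(n_meta)]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1L, eq - 1L)
      val <- substr(kv, eq + 1L, nchar(kv))
      parts <- strsplit(val, ";", fixed = TRUE)[[1L]]
      num <- suppressWarnings(as.numeric(parts))
      meta[[key]] <- if (!anyNA(num)) num else val
    }
  }
  body <- if (n_meta > 0L) lines[-seq_len(n_meta)] else lines
  if (!length(body) || trimws(body[1L]) != "time_s,displacement_mm") {
    abort("missing `time_s,displacement_mm` header.")
  }
  body <- body[-1L]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    abort("signal file contains no samples.")
  }
  df <- utils::read.csv(text = paste(c("time_s,displacement_mm", body), collapse = "\n"))
  dd <- diff(df$time_s)
  if (length(dd)) {
    dt <- dd[1L]
    bad <- which(abs(dd - dt) > 1e-6)
    if (length(bad)) {
      abort(sprintf("non-uniform sampling at row %d (time step %.8g s, expected %.8g s).",
                    bad[1L] + 1L, dd[bad[1L]], dt))
    }
  } else {
    dt <- meta$dt %||% 0.01
  }
  resp_signal(df$displacement_mm, dt = dt, t0 = df$time_s[1L], meta = meta)
}

#' Read fiducial coordinates from CSV
#'
#' Header `label,x_mm,y_mm,z_mm`, one marker per row, coordinates in mm.
#'
#' @param path Input path.
#' @param frame Coordinate-frame tag to attach (e.g. `"ct"`, `"world"`).
#' @return A [point_set()].
#' @export
read_fiducials_csv <- function(path, frame = "ct") {
  df <- utils::read.csv(path)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    abort("fiducial CSV must have columns label,x_mm,y_mm,z_mm.")
  }
  point_set(df$label, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), frame = frame)
}

#' Write or read a rigid transform as JSON
#'
#' The rotation is stored row-major under `R`, plus `t`, `scale` and the
#' fiducial `rmse`.
#'
#' @param transform A `rigid_transform`.
#' @param path JSON path.
#' @return `write_transform_json()`: `path` invisibly;
#'   `read_transform_json()`: a `rigid_transform`.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(
      R = as.numeric(t(transform$R)), t = transform$t,
      scale = transform$scale %||% 1, rmse = transform$rmse %||% NA_real_,
      n = transform$n %||% NA_integer_
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(R = matrix(obj$R, 3, 3, byrow = TRUE), t = obj$t,
         scale = obj$scale %||% 1, rmse = obj$rmse, n = obj$n),
    class = "rigid_transform"
  )
}

#' Write gating events to CSV
#'
#' Columns `t_prompt_s,t_predicted_peak_s,validated,score,mode`.
#'
#' @param events A [run_gating()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(
    tibble::as_tibble(events)[, c("t_prompt_s", "t_predicted_peak_s",
                                  "validated", "score", "mode")],
    path
  )
  invisible(path)
}

#' Write a filter trace to CSV
#'
#' Columns `time_s,xr_mm,vr_mms,c_mm,fr_hz,innovation_mm,pred_hH_mm` where
#' `H` is the configured maximum horizon.
#'
#' @param fit A [run_filter()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(fit, path) {
  tr <- fit$trace[, c("time_s", "xr_mm", "vr_mms", "c_mm", "fr_hz",
                      "innovation_mm", "pred_mm")]
  names(tr)[names(tr) == "pred_mm"] <-
    sprintf("pred_h%d_mm", fit$config$horizon_steps)
  readr::write_csv(tr, path)
  invisible(path)
}
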