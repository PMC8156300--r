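#' Construct a dual-band breathing recording
#'
#' A band recording holds the two respiratory inductance plethysmography
#' channels — rib-cage (`rc`) and abdominal (`abd`) excursion in arbitrary
#' calibrated units — sampled uniformly at `fs` Hz. It is an ordinary tibble
#' with columns `t`, `rc`, `abd` plus `fs` and `subject_id` attributes, so it
#' pipes through dplyr like any data frame; the indices functions re-derive
#' the sampling rate from `t` whenever the attribute has been dropped.
#'
#' @param data A data frame with numeric columns `t` (seconds), `rc`, `abd`.
#' @param fs Sampling rate in Hz. If `NULL`, inferred from the median spacing
#'   of `t`.
#' @param subject_id Optional subject identifier string.
#'
#' @return A `band_recording` tibble with columns `t`, `rc`, `abd`.
#' @examples
#' rec <- band_recording(
#'   data.frame(t = seq(0, 10, by = 0.02), rc = sin(seq(0, 10, by = 0.02)),
#'              abd = sin(seq(0, 10, by = 0.02))),
#'   fs = 50
#' )
#' recording_duration(rec)
#' @export
band_recording <- function(data, fs = NULL, subject_id = NA_character_) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns `t`, `rc`, `abd`.")
  }
  missing_cols <- setdiff(c("t", "rc", "abd"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Recording is missing required column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ), class = "ripasync_format_error")
  }
  out <- tibble::as_tibble(data[c("t", "rc", "abd")])
  if (nrow(out) < 2) {
    abort("A recording needs at least 2 samples.",
          class = "ripasync_format_error")
  }
  if (anyNA(out)) {
    abort("Recording contains missing values; use `read_recording()` for gap handling.",
          class = "ripasync_format_error")
  }
  dt <- diff(out$t)
  if (any(dt <= 0)) {
    abort("Time column must be strictly increasing.",
          class = "ripasync_format_error")
  }
  fs <- fs %||% (1 / median(dt))
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be a positive number.")
  # regularize to exactly uniform spacing anchored at the first timestamp
  out$t <- out$t[1] + (seq_len(nrow(out)) - 1) / fs
  structure(
    out,
    fs = fs,
    subject_id = subject_id,
    class = c("band_recording", class(tibble::tibble()))
  )
}

#' @rdname band_recording
#' @param rec A `band_recording` (or plain data frame with `t`, `rc`, `abd`).
#' @export
recording_fs <- function(rec) {
  fs <- attr(rec, "fs")
  if (!is.null(fs)) return(fs)
  1 / median(diff(rec$t))
}

#' @rdname band_recording
#' @export
recording_duration <- function(rec) {
  (nrow(rec) - 1) / recording_fs(rec)
}

#' @rdname band_recording
#' @export
recording_subject <- function(rec) {
  attr(rec, "subject_id") %||% NA_character_
}

# coerce a plain data frame to band_recording without revalidation cost
as_band_recording <- function(rec, fs = NULL) {
  if (inherits(rec, "band_recording")) return(rec)
  band_recording(rec, fs = fs)
}

#' Screen a recording for quality problems
#'
#' Applies the quality checks used during acquisition review: minimum
#' duration, flatline (zero-variance) channels, amplitude clipping (a large
#' fraction of samples pinned at the channel extremes), and residual missing
#' values. Findings are returned as data, not raised as errors, so a batch
#' run can triage recordings.
#'
#' @param rec A band recording.
#' @param min_duration_s Minimum acceptable duration in seconds.
#' @param clip_fraction Fraction of samples at a channel's extreme value
#'   above which the channel is reported as clipped.
#'
#' @return A tibble with columns `finding` and `detail`; zero rows means the
#'   recording passed every check.
#' @examples
#' rec <- simulate_breathing(duration_s = 60, seed = 1)
#' validate_recording(rec, min_duration_s = 150)
#' @export
validate_recording <- function(rec, min_duration_s = 150, clip_fraction = 0.05) {
  rec <- as_band_recording(rec)
  findings <- list()
  add <- function(finding, detail) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      finding = finding, detail = detail
    )
  }
  dur <- recording_duration(rec)
  if (dur < min_duration_s) {
    add("too_short", sprintf("duration %.1f s < minimum %.1f s", dur, min_duration_s))
  }
  for (ch in c("rc", "abd")) {
    x <- rec[[ch]]
    if (anyNA(x)) add("missing_values", ch)
    if (sd(x, na.rm = TRUE) == 0 || isTRUE(all(x == x[1]))) {
      add("flatline", ch)
      next
    }
    at_top <- mean(x == max(x, na.rm = TRUE), na.rm = TRUE)
    at_bot <- mean(x == min(x, na.rm = TRUE), na.rm = TRUE)
    if (max(at_top, at_bot) > clip_fraction) add("clipping", ch)
  }
  if (length(findings) == 0) {
    return(tibble::tibble(finding = character(), detail = character()))
  }
  dplyr::bind_rows(findings)
}

#' Extract the Konno–Mead loop of a recording
#'
#' The Konno–Mead loop plots abdominal against rib-cage excursion over one or
#' more breaths. Synchronous compartments trace a line through the origin;
#' a phase lag opens the loop (a 90° lag with equal amplitudes gives a
#' circle) and paradoxical motion flips the slope negative. Both channels
#' are mean-centered over the selected segment.
#'
#' @param rec A band recording.
#' @param from,to Optional segment bounds in seconds (recording time).
#'
#' @return A tibble with columns `t`, `rc`, `abd` (centered), of class
#'   `taa_km`, ready for `autoplot()`.
#' @examples
#' rec <- simulate_breathing(phase_lag_deg = 90, duration_s = 30, seed = 1)
#' loop <- konno_mead(rec)
#' konno_mead_area(loop)
#' @export
konno_mead <- function(rec, from = NULL, to = NULL) {
  rec <- as_band_recording(rec)
  from <- from %||% min(rec$t)
  to <- to %||% max(rec$t)
  seg <- dplyr::filter(rec, .data$t >= from, .data$t <= to)
  if (nrow(seg) < 2) abort("Konno–Mead segment is empty.")
  out <- tibble::tibble(
    t = seg$t,
    rc = seg$rc - mean(seg$rc),
    abd = seg$abd - mean(seg$abd)
  )
  structure(out, subject_id = recording_subject(rec),
            class = c("taa_km", class(tibble::tibble())))
}

#' @rdname konno_mead
#' @param loop A `taa_km` loop (or any data frame with `rc`, `abd`).
#' @details `konno_mead_area()` returns the total signed shoelace area swept
#'   by the (rc, abd) path; for sinusoidal channels of amplitudes `a`, `b`
#'   and lag `phi` it approaches `n_cycles * pi * a * b * sin(phi)` in
#'   magnitude, making it a quick asynchrony screen.
#' @export
konno_mead_area <- function(loop) {
  x <- loop$rc
  y <- loop$abd
  n <- length(x)
  if (n < 3) return(0)
  0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}
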