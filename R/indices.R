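# Shared windowing / spectral helpers -----------------------------------

# start indices of analysis windows; one whole-recording window when the
# requested window does not fit
window_starts_idx <- function(n, fs, window_s, step_s) {
  wlen <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  if (wlen >= n) return(list(starts = 1L, wlen = n))
  list(starts = seq.int(1L, n - wlen + 1L, by = step), wlen = wlen)
}

hann_taper <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# remove a least-squares linear trend
detrend_linear <- function(x) {
  n <- length(x)
  k <- seq_len(n) - (n + 1) / 2          # centered index, mean zero
  slope <- sum(k * (x - mean(x))) / sum(k * k)
  x - mean(x) - slope * k
}

# sinusoid-consistent amplitude: sqrt(2) * RMS of the detrended window;
# "peak" alternative uses half the peak-to-peak range
window_amplitude <- function(x, method = c("rms", "peak")) {
  method <- match.arg(method)
  d <- detrend_linear(x)
  if (method == "rms") sqrt(2) * sqrt(mean(d^2)) else diff(range(d)) / 2
}

# FFT of a detrended, Hann-tapered window restricted to the respiratory band
respiratory_spectrum <- function(x, fs, band = c(0.05, 2)) {
  d <- detrend_linear(x) * hann_taper(length(x))
  X <- fft(d)
  n <- length(x)
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq >= band[1] & freq <= band[2] & freq <= fs / 2
  list(X = X[keep], freq = freq[keep], power = Mod(X[keep])^2)
}

# Phase difference --------------------------------------------------------

#' Windowed cross-spectral phase difference between the bands
#'
#' Estimates the thoracoabdominal phase difference per analysis window. Each
#' window is linearly detrended, Hann-tapered and Fourier-transformed; the
#' dominant respiratory bin is the frequency in \[0.05, 2\] Hz maximising the
#' product of the two channel power spectra (so a frequency must carry energy
#' in both compartments), and the phase is the argument of the cross-spectrum
#' `RC * Conj(ABD)` at that bin. The signed phase (positive when the abdomen
#' lags the rib cage) is kept for diagnostics; the reported `phase_deg` is
#' its magnitude, folded into \[0, 180\] degrees, matching the convention
#' that asynchrony severity is unsigned.
#'
#' Windows in which either channel has zero variance are skipped with a
#' warning; an error is raised only if no window survives.
#'
#' @param rec A [band_recording()].
#' @param window_s Window length, seconds. Should cover at least three breath
#'   cycles at the subject's rate (a warning is given otherwise).
#' @param step_s Step between window starts, seconds.
#'
#' @return A tibble with one row per window: `window_start` (s), `freq_hz`
#'   (dominant respiratory frequency), `signed_phase_deg`, `phase_deg`.
#' @examples
#' rec <- simulate_breathing(rate_bpm = 15, phase_lag_deg = 90, seed = 2)
#' mean(estimate_phase(rec)$phase_deg)
#' @export
estimate_phase <- function(rec, window_s = 30, step_s = 5) {
  rec <- as_band_recording(rec)
  if (step_s > window_s) abort("`step_s` must not exceed `window_s`.")
  fs <- recording_fs(rec)
  rr <- tryCatch(estimate_rr(rec), error = function(e) NA_real_)
  if (!is.na(rr) && window_s < 3 * 60 / rr) {
    warn(sprintf(
      "Window of %.0f s covers fewer than 3 breaths at %.1f breaths/min.",
      window_s, rr))
  }
  w <- window_starts_idx(nrow(rec), fs, window_s, step_s)
  n_dead <- 0L
  rows <- purrr::map(w$starts, function(s) {
    idx <- s:(s + w$wlen - 1)
    rc <- rec$rc[idx]
    abd <- rec$abd[idx]
    if (sd(rc) == 0 || sd(abd) == 0) {
      n_dead <<- n_dead + 1L
      return(NULL)
    }
    sx <- respiratory_spectrum(rc, fs)
    sy <- respiratory_spectrum(abd, fs)
    if (length(sx$freq) == 0) return(NULL)
    peak <- which.max(sx$power * sy$power)
    cross <- sx$X[peak] * Conj(sy$X[peak])
    signed <- Arg(cross) * 180 / pi
    tibble::tibble(
      window_start = rec$t[s] - rec$t[1],
      freq_hz = sx$freq[peak],
      signed_phase_deg = signed,
      phase_deg = abs(signed)
    )
  })
  rows <- purrr::compact(rows)
  if (n_dead > 0) {
    warn(sprintf("Skipped %d zero-variance window(s).", n_dead))
  }
  if (length(rows) == 0) abort("No usable window: every window was skipped.")
  dplyr::bind_rows(rows)
}

# Amplitude-ratio indices --------------------------------------------------

#' Percentage rib-cage contribution per window
#'
#' `%RC = 100 * A_rc / (A_rc + A_abd)` per analysis window, where the
#' amplitudes are sinusoid-consistent RMS amplitudes of the linearly
#' detrended window (see [compute_lbi()] for the same estimator). Values near
#' 50% indicate the two compartments contribute equally to tidal volume, the
#' healthy pattern.
#'
#' @inheritParams estimate_phase
#' @param amp_method Amplitude estimator: `"rms"` (default, robust to single
#'   spikes) or `"peak"` (half the peak-to-peak range).
#' @return A tibble with columns `window_start`, `rc_percent`.
#' @export
compute_rc_percent <- function(rec, window_s = 30, step_s = 5,
                               amp_method = c("rms", "peak")) {
  rec <- as_band_recording(rec)
  amp_method <- match.arg(amp_method)
  fs <- recording_fs(rec)
  w <- window_starts_idx(nrow(rec), fs, window_s, step_s)
  rows <- purrr::map(w$starts, function(s) {
    idx <- s:(s + w$wlen - 1)
    a_rc <- window_amplitude(rec$rc[idx], amp_method)
    a_abd <- window_amplitude(rec$abd[idx], amp_method)
    if (a_rc + a_abd == 0) {
      warn(sprintf("Skipping dead window at t = %.1f s (both amplitudes zero).",
                   rec$t[s]))
      return(NULL)
    }
    tibble::tibble(window_start = rec$t[s] - rec$t[1],
                   rc_percent = 100 * a_rc / (a_rc + a_abd))
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) abort("No usable window: every window was skipped.")
  dplyr::bind_rows(rows)
}

#' Labored breathing index per window
#'
#' The labored breathing index compares the compartmental excursion the
#' subject *produces* with the tidal excursion it *achieves*:
#' `LBI = (A_rc + A_abd) / A_sum`, where `A_rc` and `A_abd` are the
#' single-channel amplitudes and `A_sum` is the amplitude of the summed
#' signal `rc + abd` (the tidal-volume analog). Synchronous compartments add
#' coherently, so LBI = 1; a 90° lag with equal amplitudes gives
#' `2/sqrt(2) ~ 1.414`; full paradoxical motion with equal amplitudes cancels
#' the sum and LBI diverges, reported as `Inf` with a warning. Values an
#' epsilon below 1 from floating-point noise are clipped to 1.
#'
#' @inheritParams compute_rc_percent
#' @return A tibble with columns `window_start`, `lbi`.
#' @export
compute_lbi <- function(rec, window_s = 30, step_s = 5,
                        amp_method = c("rms", "peak")) {
  rec <- as_band_recording(rec)
  amp_method <- match.arg(amp_method)
  fs <- recording_fs(rec)
  w <- window_starts_idx(nrow(rec), fs, window_s, step_s)
  n_cancel <- 0L
  rows <- purrr::map(w$starts, function(s) {
    idx <- s:(s + w$wlen - 1)
    a_rc <- window_amplitude(rec$rc[idx], amp_method)
    a_abd <- window_amplitude(rec$abd[idx], amp_method)
    a_sum <- window_amplitude(rec$rc[idx] + rec$abd[idx], amp_method)
    if (a_rc + a_abd == 0) return(NULL)
    lbi <- if (a_sum <= 1e-9 * (a_rc + a_abd)) {
      n_cancel <<- n_cancel + 1L
      Inf
    } else {
      max(1, (a_rc + a_abd) / a_sum)
    }
    tibble::tibble(window_start = rec$t[s] - rec$t[1], lbi = lbi)
  })
  rows <- purrr::compact(rows)
  if (n_cancel > 0) {
    warn(sprintf(
      "Near-total cancellation in %d window(s); LBI reported as Inf.", n_cancel))
  }
  if (length(rows) == 0) abort("No usable window: every window was skipped.")
  dplyr::bind_rows(rows)
}

# Respiratory rate ---------------------------------------------------------

#' Signal-derived respiratory rate
#'
#' Reads the breathing rate off the spectrum of the detrended, Hann-tapered
#' summed signal `rc + abd`: 60 times the frequency of the dominant peak in
#' \[0.05, 2\] Hz, refined by parabolic interpolation of log-power across the
#' peak and its two neighbours. The peak must exceed five times the median
#' in-band power, otherwise no breathing rhythm is considered detectable.
#'
#' @param rec A [band_recording()] of at least 30 s.
#' @return Respiratory rate in breaths/min (scalar).
#' @export
estimate_rr <- function(rec) {
  rec <- as_band_recording(rec)
  fs <- recording_fs(rec)
  if (recording_duration(rec) < 30) {
    abort("Rate estimation needs at least 30 s of signal.")
  }
  total <- rec$rc + rec$abd
  if (sd(total) == 0) abort("Summed signal is flat; no respiratory rhythm detectable.")
  sp <- respiratory_spectrum(total, fs)
  if (length(sp$freq) < 3) abort("Recording too short for the respiratory band.")
  peak <- which.max(sp$power)
  if (sp$power[peak] < 5 * median(sp$power)) {
    abort("No spectral peak above the noise floor in the respiratory band.")
  }
  df <- sp$freq[2] - sp$freq[1]
  delta <- 0
  if (peak > 1 && peak < length(sp$power)) {
    lp <- log(sp$power[(peak - 1):(peak + 1)] + .Machine$double.xmin)
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (denom < 0) delta <- 0.5 * (lp[1] - lp[3]) / denom
  }
  60 * (sp$freq[peak] + delta * df)
}

# Aggregator ---------------------------------------------------------------

#' Compute the full respiratory index series of a recording
#'
#' Runs [estimate_phase()], [compute_rc_percent()], [compute_lbi()] and
#' [estimate_rr()] on a shared window grid and joins the per-window results.
#' The recording-level respiratory rate, window settings, sampling rate and
#' subject id travel as attributes; `glance()`-style summaries are available
#' via [summarise_indices()].
#'
#' @inheritParams compute_rc_percent
#' @return A `taa_indices` tibble with columns `window_start`, `phase_deg`,
#'   `signed_phase_deg`, `freq_hz`, `rc_percent`, `lbi`, and attributes
#'   `rr_bpm`, `window_s`, `step_s`, `subject_id`.
#' @examples
#' rec <- simulate_breathing(rate_bpm = 18, phase_lag_deg = 120, seed = 3)
#' idx <- compute_indices(rec)
#' summarise_indices(idx)
#' @export
compute_indices <- function(rec, window_s = 30, step_s = 5,
                            amp_method = c("rms", "peak")) {
  rec <- as_band_recording(rec)
  amp_method <- match.arg(amp_method)
  ph <- estimate_phase(rec, window_s, step_s)
  rcp <- compute_rc_percent(rec, window_s, step_s, amp_method)
  lbi <- compute_lbi(rec, window_s, step_s, amp_method)
  out <- ph |>
    dplyr::inner_join(rcp, by = "window_start") |>
    dplyr::inner_join(lbi, by = "window_start")
  structure(
    out,
    rr_bpm = estimate_rr(rec),
    window_s = window_s,
    step_s = step_s,
    subject_id = recording_subject(rec),
    class = c("taa_indices", class(tibble::tibble()))
  )
}

#' @rdname compute_indices
#' @param indices A `taa_indices` tibble.
#' @export
summarise_indices <- function(indices) {
  tibble::tibble(
    subject_id = attr(indices, "subject_id") %||% NA_character_,
    n_windows = nrow(indices),
    rr_bpm = attr(indices, "rr_bpm") %||% NA_real_,
    mean_phase_deg = mean(indices$phase_deg),
    median_phase_deg = median(indices$phase_deg),
    mean_rc_percent = mean(indices$rc_percent),
    mean_lbi = mean(indices$lbi)
  )
}

#' Write / read an index series as CSV (with a JSON sidecar for the rate)
#'
#' @param indices A `taa_indices` tibble.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json` holding `rr_bpm`, `window_s`, `step_s`, `subject_id`.
#' @return `write_indices()` invisibly returns `path`; `read_indices()`
#'   returns the `taa_indices` tibble.
#' @export
write_indices <- function(indices, path) {
  readr::write_csv(tibble::as_tibble(indices), path, progress = FALSE)
  meta <- list(
    rr_bpm = attr(indices, "rr_bpm"),
    window_s = attr(indices, "window_s"),
    step_s = attr(indices, "step_s"),
    subject_id = attr(indices, "subject_id")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_indices
#' @export
read_indices <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(
    df,
    rr_bpm = meta$rr_bpm %||% NA_real_,
    window_s = meta$window_s %||% NA_real_,
    step_s = meta$step_s %||% NA_real_,
    subject_id = meta$subject_id %||% NA_character_,
    class = c("taa_indices", class(tibble::tibble()))
  )
}
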