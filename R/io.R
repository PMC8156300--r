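#' Read and write dual-band recordings as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with header `t,rc,abd`: time in
#' seconds and the two band excursions in arbitrary calibrated units. Small
#' gaps (at most 5% missing samples per channel) are filled by linear
#' interpolation with a warning; larger gaps are rejected as a quality
#' failure. Writing then reading a recording reproduces the signal values
#' exactly.
#'
#' @param path File path.
#' @param fs_override Optional sampling rate in Hz; when `NULL` the rate is
#'   inferred from the median time-step.
#' @param subject_id Optional subject identifier attached to the recording.
#' @param max_na_fraction Largest tolerated fraction of missing samples per
#'   channel before the file is rejected.
#'
#' @return `read_recording()` returns a [band_recording()];
#'   `write_recording()` invisibly returns `path`.
#' @examples
#' rec <- simulate_breathing(duration_s = 10, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_recording(rec, f)
#' rec2 <- read_recording(f)
#' all.equal(rec$rc, rec2$rc)
#' @export
read_recording <- function(path, fs_override = NULL,
                           subject_id = NA_character_,
                           max_na_fraction = 0.05) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  # base read.csv parses doubles via strtod (correctly rounded), so values
  # written by write_recording come back bit-equal
  df <- utils::read.csv(path)
  missing_cols <- setdiff(c("t", "rc", "abd"), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Recording CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "ripasync_format_error")
  }
  for (ch in c("t", "rc", "abd")) {
    if (!is.numeric(df[[ch]])) {
      abort(paste0("Column ", ch, " is not numeric."),
            class = "ripasync_format_error")
    }
  }
  if (anyNA(df$t) || is.unsorted(df$t, strictly = TRUE)) {
    abort("Time column must be complete and strictly increasing.",
          class = "ripasync_format_error")
  }
  for (ch in c("rc", "abd")) {
    frac <- mean(is.na(df[[ch]]))
    if (frac > max_na_fraction) {
      abort(sprintf("Channel %s has %.1f%% missing samples (limit %.0f%%).",
                    ch, 100 * frac, 100 * max_na_fraction),
            class = "ripasync_quality_error")
    }
    if (frac > 0) {
      warn(sprintf("Interpolating %.2f%% missing samples in channel %s.",
                   100 * frac, ch))
      df[[ch]] <- approx(df$t, df[[ch]], xout = df$t, rule = 2)$y
    }
  }
  band_recording(df, fs = fs_override, subject_id = subject_id)
}

#' @rdname read_recording
#' @param rec A [band_recording()].
#' @export
write_recording <- function(rec, path) {
  rec <- as_band_recording(rec)
  # 17 significant digits guarantee an exact double round-trip
  lines <- sprintf("%.17g,%.17g,%.17g", rec$t, rec$rc, rec$abd)
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(c("t,rc,abd", lines), con, sep = "\n")
  invisible(path)
}

#' Read and write vital-sign summaries as JSON
#'
#' A vitals file holds one object (or an array of objects) with fields
#' `subject_id`, `rr` (breaths/min), `etco2` (mmHg), `spo2` (%), `hr`
#' (beats/min) and `age_years`; any measurement may be `null` when the
#' monitor did not record it.
#'
#' @param path File path.
#' @return `read_vitals()` returns a tibble with one row per subject and the
#'   fields above (`NA` where absent); `write_vitals()` invisibly returns
#'   `path`.
#' @export
read_vitals <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(names(raw))) raw <- list(raw)  # single object, not an array
  rows <- purrr::map_dfr(raw, function(v) {
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    tibble::tibble(
      subject_id = if (is.null(v$subject_id)) NA_character_ else as.character(v$subject_id),
      age_years = num(v$age_years),
      rr = num(v$rr), etco2 = num(v$etco2), spo2 = num(v$spo2), hr = num(v$hr)
    )
  })
  bad_spo2 <- !is.na(rows$spo2) & (rows$spo2 < 0 | rows$spo2 > 100)
  if (any(bad_spo2)) abort("SpO2 values must lie in [0, 100].")
  neg <- c("rr", "etco2", "hr")
  for (f in neg) {
    if (any(!is.na(rows[[f]]) & rows[[f]] < 0)) {
      abort(paste0("Negative ", f, " value in vitals file."))
    }
  }
  rows
}

#' @rdname read_vitals
#' @param vitals A data frame of vitals rows as returned by `read_vitals()`
#'   or [simulate_vitals()].
#' @export
write_vitals <- function(vitals, path) {
  recs <- purrr::transpose(as.list(vitals))
  recs <- purrr::map(recs, ~ purrr::map(.x, function(v) if (is.na(v)) NULL else v))
  if (length(recs) == 1) recs <- recs[[1]]
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
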