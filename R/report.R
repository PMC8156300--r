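#' Flag a value against a healthy reference
#'
#' `flag_by_deviation()` implements the relative-deviation rule used for
#' respiratory indices: a value is abnormal when it deviates from the
#' age-matched healthy mean by more than `deviation_fraction` (default 20%)
#' of that mean. Boundary values (exactly 20% off) count as normal. The rule
#' can be one-sided (`side = "above"`: only elevated values are abnormal),
#' which is how the phase difference and labored breathing index are read —
#' below-mean values of either are not a dysfunction signal.
#'
#' `flag_by_range()` flags a value outside a closed healthy interval, as for
#' end-tidal CO2 (35–45 mmHg); `flag_spo2()` applies the strictly-greater
#' oxygen-saturation rule (normal requires SpO2 > 95%).
#'
#' All three are total over missing input: `NA` yields `"unavailable"`.
#'
#' @param value Measured value (may be `NA`).
#' @param healthy_mean Age-matched healthy mean (> 0).
#' @param deviation_fraction Allowed relative deviation, in (0, 1).
#' @param side `"both"` or `"above"`.
#' @return One of `"normal"`, `"abnormal"`, `"unavailable"`.
#' @examples
#' flag_by_deviation(24, 20)        # 20% above: still normal
#' flag_by_deviation(24.1, 20)      # beyond 20%: abnormal
#' flag_by_range(46, 35, 45)
#' flag_spo2(95)
#' @export
flag_by_deviation <- function(value, healthy_mean,
                              deviation_fraction = 0.2,
                              side = c("both", "above")) {
  side <- match.arg(side)
  if (is.na(healthy_mean) || healthy_mean <= 0) {
    abort("`healthy_mean` must be a positive number.")
  }
  if (deviation_fraction <= 0 || deviation_fraction >= 1) {
    abort("`deviation_fraction` must lie in (0, 1).")
  }
  if (is.null(value) || is.na(value)) return("unavailable")
  dev <- (value - healthy_mean) / healthy_mean
  abnormal <- if (side == "both") abs(dev) > deviation_fraction
              else dev > deviation_fraction
  if (abnormal) "abnormal" else "normal"
}

#' @rdname flag_by_deviation
#' @param lo,hi Closed healthy range bounds (`lo <= hi`).
#' @export
flag_by_range <- function(value, lo, hi) {
  if (lo > hi) abort("`lo` must not exceed `hi`.")
  if (is.null(value) || is.na(value)) return("unavailable")
  if (value >= lo && value <= hi) "normal" else "abnormal"
}

#' @rdname flag_by_deviation
#' @param min_pct Saturation floor; normal requires strictly greater.
#' @export
flag_spo2 <- function(value, min_pct = 95) {
  if (is.null(value) || is.na(value)) return("unavailable")
  if (value > min_pct) "normal" else "abnormal"
}

#' Healthy reference values by age
#'
#' Reads (or constructs) the per-age healthy reference table used for the
#' deviation flags: for each age band, the healthy mean respiratory rate,
#' %RC, labored breathing index and phase difference, plus the fixed
#' end-tidal CO2 range, the SpO2 floor and the deviation fraction. The table
#' shipped with the package (`reference_ranges_synthetic.json`) contains
#' synthetic placeholder values on physiologically plausible scales — sites
#' should substitute means from their own healthy reference population.
#'
#' @param path Path to a reference-ranges JSON file; default is the packaged
#'   synthetic table.
#' @return A list with elements `deviation_fraction`, `etco2_range`,
#'   `spo2_min` and `ages` (a tibble with columns `age_min`, `age_max`,
#'   `rr_mean`, `rc_percent_mean`, `lbi_mean`, `phase_mean`).
#' @export
read_reference_ranges <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference_ranges_synthetic.json",
                                package = "ripasync", mustWork = TRUE)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ages <- tibble::as_tibble(raw$ages)
  needed <- c("age_min", "age_max", "rr_mean", "rc_percent_mean",
              "lbi_mean", "phase_mean")
  missing_f <- setdiff(needed, names(ages))
  if (length(missing_f) > 0) {
    abort(paste0("Reference table is missing column(s): ",
                 paste(missing_f, collapse = ", "), "."))
  }
  if (any(ages$age_min > ages$age_max)) abort("Ill-ordered age band in reference table.")
  er <- as.numeric(raw$etco2_range %||% c(35, 45))
  if (er[1] > er[2]) abort("Ill-ordered etco2_range in reference table.")
  list(
    deviation_fraction = raw$deviation_fraction %||% 0.2,
    etco2_range = er,
    spo2_min = raw$spo2_min %||% 95,
    ages = ages
  )
}

# reference row covering an age, or NULL
reference_for_age <- function(refs, age_years) {
  if (is.na(age_years)) return(NULL)
  hit <- dplyr::filter(refs$ages, age_years >= .data$age_min,
                       age_years <= .data$age_max)
  if (nrow(hit) == 0) NULL else hit[1, ]
}

#' Assemble a per-subject assessment report
#'
#' Combines everything known about one subject into a single flag row:
#' deviation flags for the signal-derived indices (respiratory rate two-sided
#' against the age-matched healthy mean; %RC two-sided; LBI and mean phase
#' one-sided above, since only elevation marks dysfunction), range flags for
#' the vital signs, the ICP classifier verdict, and pass-through clinical
#' metadata. Anything unmeasured — absent vitals, an age outside the
#' reference table, no classifier — degrades to `"unavailable"` rather than
#' failing.
#'
#' @param indices A `taa_indices` tibble from [compute_indices()].
#' @param vitals Optional one-row vitals tibble ([simulate_vitals()] /
#'   [read_vitals()]); its `rr` takes precedence over the signal-derived
#'   rate.
#' @param verdict Optional classifier output for the subject: a one-row
#'   tibble from [predict.taa_enet()] (or a label string).
#' @param refs Reference ranges from [read_reference_ranges()].
#' @param age_years Subject age (used to pick the reference band).
#' @param subject_id Identifier; defaults to the one on `indices`.
#' @param clinical_diagnosis,surgery Pass-through metadata strings.
#' @param phase_side,lbi_side,rc_side,rr_side Sidedness of each deviation
#'   flag (`"above"` or `"both"`).
#' @return A one-row `taa_report` tibble: identifiers, the measured summary
#'   values, and flags `rr_flag`, `etco2_flag`, `spo2_flag`, `rc_flag`,
#'   `lbi_flag`, `phase_flag`, `icp_flag`, each `"normal"`, `"abnormal"` or
#'   `"unavailable"`.
#' @export
build_report <- function(indices, vitals = NULL, verdict = NULL,
                         refs = read_reference_ranges(),
                         age_years = NA_real_,
                         subject_id = NULL,
                         clinical_diagnosis = NA_character_,
                         surgery = NA_character_,
                         phase_side = "above", lbi_side = "above",
                         rc_side = "both", rr_side = "both") {
  s <- summarise_indices(indices)
  subject_id <- subject_id %||% s$subject_id
  if (is.null(vitals)) {
    vitals <- tibble::tibble(rr = NA_real_, etco2 = NA_real_,
                             spo2 = NA_real_, hr = NA_real_)
  }
  if (is.na(age_years) && "age_years" %in% names(vitals)) {
    age_years <- vitals$age_years[1]
  }
  ref <- reference_for_age(refs, age_years)
  if (is.null(ref)) {
    inform(sprintf(
      "No reference band covers age %s; index flags set to 'unavailable'.",
      format(age_years)))
  }
  rr_val <- if (!is.na(vitals$rr[1])) vitals$rr[1] else s$rr_bpm
  dev_flag <- function(value, mean_col, side) {
    if (is.null(ref)) return("unavailable")
    flag_by_deviation(value, ref[[mean_col]], refs$deviation_fraction, side)
  }
  icp_flag <- if (is.null(verdict)) {
    "unavailable"
  } else if (is.data.frame(verdict)) {
    verdict$label[1]
  } else {
    as.character(verdict)
  }
  out <- tibble::tibble(
    subject_id = subject_id,
    age_years = age_years,
    rr_bpm = rr_val,
    etco2 = vitals$etco2[1],
    spo2 = vitals$spo2[1],
    mean_rc_percent = s$mean_rc_percent,
    mean_lbi = s$mean_lbi,
    mean_phase_deg = s$mean_phase_deg,
    rr_flag = dev_flag(rr_val, "rr_mean", rr_side),
    etco2_flag = flag_by_range(vitals$etco2[1], refs$etco2_range[1],
                               refs$etco2_range[2]),
    spo2_flag = flag_spo2(vitals$spo2[1], refs$spo2_min),
    rc_flag = dev_flag(s$mean_rc_percent, "rc_percent_mean", rc_side),
    lbi_flag = dev_flag(s$mean_lbi, "lbi_mean", lbi_side),
    phase_flag = dev_flag(s$mean_phase_deg, "phase_mean", phase_side),
    icp_flag = icp_flag,
    clinical_diagnosis = clinical_diagnosis,
    surgery = surgery
  )
  class(out) <- c("taa_report", class(out))
  out
}

#' Write / read assessment reports
#'
#' Reports serialize as a JSON array (lossless, `NA` kept as `null`) with a
#' CSV rendering alongside when `csv_path` is given.
#'
#' @param reports A `taa_report` tibble (one or more rows).
#' @param path JSON path.
#' @param csv_path Optional CSV path for the tabular rendering.
#' @return `write_reports()` invisibly returns `path`; `read_reports()` the
#'   restored tibble.
#' @export
write_reports <- function(reports, path, csv_path = NULL) {
  jsonlite::write_json(tibble::as_tibble(reports), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (!is.null(csv_path)) {
    readr::write_csv(tibble::as_tibble(reports), csv_path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  class(df) <- c("taa_report", class(df))
  df
}
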