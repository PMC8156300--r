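#' Simulate a two-band breathing recording
#'
#' Generates rib-cage and abdominal excursion channels as sinusoids sharing
#' one instantaneous breathing rate, with the abdomen delayed by a fixed
#' phase lag:
#' \deqn{rc(t) = A_{rc}\sin\theta(t) + d\,t + \epsilon_{rc}(t)}
#' \deqn{abd(t) = A_{abd}\sin(\theta(t) - \phi) + d\,t + \epsilon_{abd}(t)}
#' where \eqn{\theta(t)} integrates the instantaneous rate. Breath-to-breath
#' rate variability is an Ornstein–Uhlenbeck perturbation (10 s correlation
#' time) of the nominal rate, which avoids the discontinuities a per-breath
#' resampling scheme would introduce. Quiet tidal breathing corresponds to a
#' small lag and near-equal amplitudes; asynchronous (resistively loaded or
#' dysfunctional) breathing to a large lag and unequal amplitudes.
#'
#' All randomness flows through R's Mersenne-Twister generator seeded with
#' `seed`; identical arguments give identical recordings on any platform.
#'
#' @param rate_bpm Nominal breathing rate, breaths/min.
#' @param amp_rc,amp_abd Channel amplitudes, arbitrary units.
#' @param phase_lag_deg Abdominal lag behind the rib cage, degrees in
#'   \[0, 180\]; 0 is synchronous, 180 paradoxical.
#' @param noise_sd Additive white-noise SD per channel, arbitrary units.
#' @param drift_per_min Shared linear baseline drift, units/min.
#' @param rate_jitter_sd Stationary SD of the rate perturbation, breaths/min.
#' @param duration_s Recording length, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer RNG seed.
#' @param subject_id Subject identifier carried on the recording.
#'
#' @return A [band_recording()].
#' @examples
#' rec <- simulate_breathing(rate_bpm = 20, phase_lag_deg = 90,
#'                           duration_s = 60, seed = 7)
#' estimate_rr(rec)
#' @export
simulate_breathing <- function(rate_bpm = 15, amp_rc = 1, amp_abd = 1,
                               phase_lag_deg = 0, noise_sd = 0,
                               drift_per_min = 0, rate_jitter_sd = 0,
                               duration_s = 180, fs = 50, seed = 1,
                               subject_id = NA_character_) {
  if (rate_bpm <= 0) abort("`rate_bpm` must be positive.")
  if (amp_rc < 0 || amp_abd < 0) abort("Amplitudes must be non-negative.")
  if (amp_rc + amp_abd <= 0) abort("At least one compartment must move.")
  if (phase_lag_deg < 0 || phase_lag_deg > 180) {
    abort("`phase_lag_deg` must lie in [0, 180].")
  }
  if (noise_sd < 0 || rate_jitter_sd < 0) abort("SD parameters must be >= 0.")
  if (duration_s <= 0 || fs <= 0) abort("`duration_s` and `fs` must be positive.")

  n <- floor(duration_s * fs) + 1
  t <- (seq_len(n) - 1) / fs
  f0 <- rate_bpm / 60

  withr::local_seed(seed)
  if (rate_jitter_sd > 0) {
    # OU process: AR(1) with correlation time tau, stationary sd in Hz
    tau <- 10
    a <- exp(-1 / (fs * tau))
    sd_eq <- rate_jitter_sd / 60
    eps <- rnorm(n, 0, sd_eq * sqrt(1 - a^2))
    j <- Reduce(function(prev, e) a * prev + e, eps[-1],
                init = rnorm(1, 0, sd_eq), accumulate = TRUE)
    f_inst <- pmax(f0 + j, 0.05)
  } else {
    f_inst <- rep(f0, n)
  }
  theta <- 2 * pi * cumsum(f_inst) / fs
  theta <- theta - theta[1]
  lag_rad <- phase_lag_deg * pi / 180
  drift <- drift_per_min * t / 60
  rc <- amp_rc * sin(theta) + drift +
    if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  abd <- amp_abd * sin(theta - lag_rad) + drift +
    if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0

  band_recording(tibble::tibble(t = t, rc = rc, abd = abd),
                 fs = fs, subject_id = subject_id)
}

#' Default sampling ranges for simulated cohorts
#'
#' The two condition profiles mirror a training design in which healthy
#' subjects are recorded twice, once breathing quietly and once through a
#' resistive load that induces thoracoabdominal asynchrony. Normal draws use
#' a low phase lag (0–30°) and near-equal compartment amplitudes; abnormal
#' draws a high lag (60–180°) and an imbalanced amplitude split. Each field
#' is a `c(lo, hi)` interval sampled uniformly.
#'
#' @param label `"normal"` or `"abnormal"`.
#' @return A named list of `c(lo, hi)` intervals.
#' @export
cohort_param_ranges <- function(label = c("normal", "abnormal")) {
  label <- match.arg(label)
  if (label == "normal") {
    list(
      rate_bpm = c(12, 22), amp_rc = c(0.9, 1.1), amp_abd = c(0.9, 1.1),
      phase_lag_deg = c(0, 30), noise_sd = c(0.01, 0.03),
      drift_per_min = c(-0.05, 0.05), rate_jitter_sd = c(0.3, 1)
    )
  } else {
    list(
      rate_bpm = c(12, 25), amp_rc = c(0.6, 1.4), amp_abd = c(0.6, 1.4),
      phase_lag_deg = c(60, 180), noise_sd = c(0.01, 0.03),
      drift_per_min = c(-0.05, 0.05), rate_jitter_sd = c(0.3, 1.5)
    )
  }
}

#' Simulate a labelled cohort of breathing recordings
#'
#' Draws per-subject generator parameters uniformly from per-label intervals
#' and simulates each recording. Sub-seeds are derived from the master seed
#' by `(seed + 7919 * i) mod (2^31 - 1)` over the subject index `i`, so any
#' subject's recording can be regenerated in isolation.
#'
#' @param n_normal,n_abnormal Number of subjects per condition.
#' @param seed Master integer seed.
#' @param normal_ranges,abnormal_ranges Named lists of `c(lo, hi)` sampling
#'   intervals overriding [cohort_param_ranges()] fields.
#' @param duration_s,fs Recording length and sampling rate passed to every
#'   subject.
#'
#' @return A tibble with one row per subject: `subject_id`, `label`,
#'   `params` (list-column of generator arguments) and `recording`
#'   (list-column of [band_recording()]s).
#' @examples
#' cohort <- simulate_cohort(n_normal = 2, n_abnormal = 2, seed = 1,
#'                           duration_s = 60)
#' cohort$label
#' @export
simulate_cohort <- function(n_normal = 10, n_abnormal = 10, seed = 1,
                            normal_ranges = list(), abnormal_ranges = list(),
                            duration_s = 180, fs = 50) {
  if (n_normal < 0 || n_abnormal < 0) abort("Cohort sizes must be >= 0.")
  ranges <- list(
    normal = modifyList(cohort_param_ranges("normal"), normal_ranges),
    abnormal = modifyList(cohort_param_ranges("abnormal"), abnormal_ranges)
  )
  for (lab in names(ranges)) {
    bad <- purrr::keep(ranges[[lab]], ~ .x[2] < .x[1])
    if (length(bad) > 0) {
      abort(paste0("Ill-ordered sampling interval(s) for ", lab, ": ",
                   paste(names(bad), collapse = ", "), "."))
    }
  }
  if (ranges$normal$phase_lag_deg[2] > ranges$abnormal$phase_lag_deg[1]) {
    inform("Normal and abnormal phase-lag intervals overlap; the labels may not be separable.")
  }
  labels <- c(rep("normal", n_normal), rep("abnormal", n_abnormal))
  purrr::imap_dfr(labels, function(lab, i) {
    sub_seed <- as.integer((seed + 7919 * i) %% (2^31 - 1))
    rng <- ranges[[lab]]
    p <- withr::with_seed(sub_seed, purrr::map(rng, ~ runif(1, .x[1], .x[2])))
    p$duration_s <- duration_s
    p$fs <- fs
    p$seed <- sub_seed + 1L
    p$subject_id <- sprintf("S%02d_%s", i, lab)
    tibble::tibble(
      subject_id = p$subject_id,
      label = lab,
      params = list(p),
      recording = list(do.call(simulate_breathing, p))
    )
  })
}

#' Simulate per-subject vital-sign summaries
#'
#' Normal subjects draw end-tidal CO2 inside the healthy 35–45 mmHg range and
#' oxygen saturation above 95%; abnormal subjects may fall outside both, with
#' an elevated respiratory rate relative to the age-typical value. Heart rate
#' scales down with age as in standard pediatric reference tables.
#'
#' @param label `"normal"` or `"abnormal"`.
#' @param age_years Subject age in years.
#' @param seed Integer seed.
#' @param subject_id Identifier carried into the output.
#' @return A one-row tibble: `subject_id`, `age_years`, `rr`, `etco2`,
#'   `spo2`, `hr`.
#' @export
simulate_vitals <- function(label = c("normal", "abnormal"), age_years = 12,
                            seed = 1, subject_id = NA_character_) {
  label <- match.arg(label)
  if (age_years < 0) abort("`age_years` must be >= 0.")
  rr_typ <- healthy_rr_for_age(age_years)
  withr::with_seed(seed, {
    if (label == "normal") {
      tibble::tibble(
        subject_id = subject_id,
        age_years = age_years,
        rr = runif(1, 0.9, 1.1) * rr_typ,
        etco2 = runif(1, 36, 44),
        spo2 = runif(1, 96.5, 99.5),
        hr = runif(1, 0.9, 1.1) * (110 - 2 * pmin(age_years, 20))
      )
    } else {
      tibble::tibble(
        subject_id = subject_id,
        age_years = age_years,
        rr = runif(1, 1.25, 1.6) * rr_typ,
        etco2 = sample(c(runif(1, 28, 34), runif(1, 46, 55)), 1),
        spo2 = runif(1, 88, 97),
        hr = runif(1, 1.0, 1.3) * (110 - 2 * pmin(age_years, 20))
      )
    }
  })
}

# age-typical resting respiratory rate (breaths/min), piecewise by age band
healthy_rr_for_age <- function(age_years) {
  brks <- c(0, 1, 3, 6, 12, 18, Inf)
  vals <- c(40, 28, 24, 20, 16, 14)
  vals[findInterval(age_years, brks, rightmost.closed = TRUE)]
}
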