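test_that("deviation rule flags with inclusive 20% boundaries", {
  expect_identical(flag_by_deviation(20, 20), "normal")
  expect_identical(flag_by_deviation(24, 20), "normal")        # +20% inclusive
  expect_identical(flag_by_deviation(24.0001, 20), "abnormal")
  expect_identical(flag_by_deviation(16, 20), "normal")        # -20% inclusive
  expect_identical(flag_by_deviation(15.9999, 20), "abnormal")
  # one-sided reading: depressed values are not abnormal
  expect_identical(flag_by_deviation(10, 20, side = "above"), "normal")
  expect_identical(flag_by_deviation(30, 20, side = "above"), "abnormal")
  expect_identical(flag_by_deviation(NA, 20), "unavailable")
  expect_error(flag_by_deviation(10, 0), "positive")
  expect_error(flag_by_deviation(10, 20, deviation_fraction = 1.5), "0, 1")
})

test_that("range and saturation rules use the documented boundary conventions", {
  expect_identical(flag_by_range(40, 35, 45), "normal")
  expect_identical(flag_by_range(35, 35, 45), "normal")   # inclusive
  expect_identical(flag_by_range(45, 35, 45), "normal")   # inclusive
  expect_identical(flag_by_range(46, 35, 45), "abnormal")
  expect_identical(flag_by_range(34.9, 35, 45), "abnormal")
  expect_identical(flag_by_range(NA, 35, 45), "unavailable")
  expect_error(flag_by_range(40, 45, 35), "lo")

  expect_identical(flag_spo2(96), "normal")
  expect_identical(flag_spo2(95), "abnormal")   # strictly greater required
  expect_identical(flag_spo2(94), "abnormal")
  expect_identical(flag_spo2(NA), "unavailable")
})

test_that("reference table loads, validates and resolves ages", {
  refs <- read_reference_ranges()
  expect_equal(refs$etco2_range, c(35, 45))
  expect_equal(refs$spo2_min, 95)
  expect_equal(refs$deviation_fraction, 0.2)
  expect_true(all(c("rr_mean", "phase_mean") %in% names(refs$ages)))

  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(ages = list(list(age_min = 0, age_max = 10))), f,
                       auto_unbox = TRUE)
  expect_error(read_reference_ranges(f), "missing column")
})

test_that("a synthetic normal subject reports all-normal flags", {
  rec <- simulate_breathing(rate_bpm = 16, phase_lag_deg = 5, noise_sd = 0.02,
                            duration_s = 120, seed = 51)
  idx <- compute_indices(rec)
  vitals <- simulate_vitals("normal", age_years = 14, seed = 51)
  rep1 <- build_report(idx, vitals = vitals, verdict = "normal",
                       age_years = 14, subject_id = "N1")
  flags <- unlist(rep1[grepl("_flag$", names(rep1))])
  expect_true(all(flags == "normal"))
})

test_that("an asynchronous subject is flagged on phase and ICP", {
  rec <- simulate_breathing(rate_bpm = 16, phase_lag_deg = 120,
                            noise_sd = 0.02, duration_s = 120, seed = 52)
  idx <- compute_indices(rec)
  vitals <- simulate_vitals("normal", age_years = 14, seed = 52)
  rep1 <- build_report(idx, vitals = vitals,
                       verdict = tibble::tibble(probability = 0.99,
                                                label = "abnormal"),
                       age_years = 14, subject_id = "A1")
  expect_identical(rep1$phase_flag, "abnormal")
  expect_identical(rep1$lbi_flag, "abnormal")
  expect_identical(rep1$icp_flag, "abnormal")
})

test_that("missing vitals and uncovered ages degrade to unavailable", {
  idx <- compute_indices(simulate_breathing(duration_s = 90, seed = 53))
  rep1 <- build_report(idx, vitals = NULL, verdict = NULL, age_years = 14)
  expect_identical(rep1$etco2_flag, "unavailable")
  expect_identical(rep1$spo2_flag, "unavailable")
  expect_identical(rep1$icp_flag, "unavailable")
  # rr falls back to the signal-derived rate, so it can still be flagged
  expect_true(rep1$rr_flag %in% c("normal", "abnormal"))

  expect_message(
    rep2 <- build_report(idx, vitals = NULL, age_years = 300),
    "No reference band")
  expect_identical(rep2$phase_flag, "unavailable")
  expect_identical(rep2$rc_flag, "unavailable")
})

test_that("reports round-trip through JSON and CSV", {
  idx <- compute_indices(simulate_breathing(duration_s = 90, seed = 54))
  vitals <- simulate_vitals("normal", age_years = 10, seed = 54)
  rep1 <- build_report(idx, vitals = vitals, verdict = "normal",
                       age_years = 10, subject_id = "S1",
                       clinical_diagnosis = "no respiratory issues",
                       surgery = "none")
  f <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_reports(rep1, f, csv_path = fc)
  back <- read_reports(f)
  expect_equal(as.data.frame(back), as.data.frame(rep1))
  expect_true(file.exists(fc))
  csv <- readr::read_csv(fc, col_types = readr::cols(), progress = FALSE)
  expect_identical(csv$subject_id, "S1")
  expect_identical(csv$surgery, "none")
})

test_that("flag counts on a seeded cohort are reproducible", {
  run_once <- function() {
    cohort <- simulate_cohort(n_normal = 2, n_abnormal = 2, seed = 55,
                              duration_s = 90)
    reports <- dplyr::bind_rows(purrr::imap(cohort$recording, function(r, i) {
      build_report(compute_indices(r),
                   vitals = simulate_vitals(cohort$label[i], 12, seed = 55 + i),
                   verdict = cohort$label[i], age_years = 12,
                   subject_id = cohort$subject_id[i])
    }))
    table(unlist(reports[grepl("_flag$", names(reports))]))
  }
  expect_identical(run_once(), run_once())
})
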