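#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with any
#' supplied overrides merged in. Fields: `seed`, `fs`, `duration_s`,
#' `window_s`, `step_s`, `feature_step_deg`, `alpha`, `n_folds`, `threshold`,
#' `cohort` (`n_normal`, `n_abnormal` training subjects), `assess`
#' (`n_normal`, `n_abnormal` assessment subjects), `refs_path` (`NULL` for
#' the packaged synthetic reference table) and `out_dir`.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    fs = 50,
    duration_s = 180,
    window_s = 30,
    step_s = 5,
    feature_step_deg = 5,
    alpha = 0.5,
    n_folds = 10,
    threshold = 0.5,
    cohort = list(n_normal = 10, n_abnormal = 10),
    assess = list(n_normal = 5, n_abnormal = 5),
    refs_path = NULL,
    out_dir = "taa_run"
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  modifyList(cfg, overrides)
}

#' Run the full assessment pipeline end to end
#'
#' Simulates a labelled training cohort, computes per-subject indices and
#' ICP curves, trains the elastic-net classifier, then simulates a fresh
#' assessment cohort (seed offset by 10000), predicts each subject and
#' assembles flag reports. All artifacts are written under
#' `config$out_dir`:
#' recordings (`recordings/<id>.csv`), `labels.csv`, per-subject indices and
#' ICP curves, `features.csv`, `model.json`, `envelopes.csv`,
#' `predictions.csv`, `vitals.json`, and `reports.json` / `reports.csv`.
#' Identical config and seed give byte-identical artifacts.
#'
#' @param config A configuration list from [pipeline_config()] or a path to
#'   a JSON file with the same fields.
#' @param seed Optional integer overriding `config$seed`.
#' @param out_dir Optional output directory overriding `config$out_dir`.
#' @return Invisibly, a list with the fitted `model`, the training
#'   `features`, the assessment `predictions` and `reports`, and the
#'   artifact directory.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("No such config file: ", config))
    config <- pipeline_config(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(out_dir)) config$out_dir <- out_dir

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "ripasync_stage_error")
    })
  }

  out <- config$out_dir
  dir.create(file.path(out, "recordings"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "indices"), showWarnings = FALSE)
  dir.create(file.path(out, "icp"), showWarnings = FALSE)

  refs <- stage("references", read_reference_ranges(config$refs_path))
  grid <- seq(0, 180, by = config$feature_step_deg)

  analyse_cohort <- function(cohort, tag) {
    purrr::pmap(cohort, function(subject_id, label, params, recording) {
      write_recording(recording, file.path(out, "recordings",
                                           paste0(subject_id, ".csv")))
      idx <- compute_indices(recording, config$window_s, config$step_s)
      write_indices(idx, file.path(out, "indices", paste0(subject_id, ".csv")))
      curve <- compute_icp(idx)
      write_icp(curve, file.path(out, "icp", paste0(subject_id, ".csv")))
      list(subject_id = subject_id, label = label, indices = idx,
           curve = curve,
           features = icp_features(curve, grid))
    })
  }

  inform("Simulating training cohort...")
  train_cohort <- stage("simulate", simulate_cohort(
    n_normal = config$cohort$n_normal, n_abnormal = config$cohort$n_abnormal,
    seed = config$seed, duration_s = config$duration_s, fs = config$fs
  ))
  train_cohort$subject_id <- paste0("train_", train_cohort$subject_id)
  readr::write_csv(train_cohort[c("subject_id", "label")],
                   file.path(out, "labels.csv"), progress = FALSE)

  inform("Computing indices and ICP curves...")
  train <- stage("analyze", analyse_cohort(train_cohort, "train"))
  features <- dplyr::bind_rows(purrr::map(train, "features"))
  features <- dplyr::bind_cols(
    tibble::tibble(subject_id = purrr::map_chr(train, "subject_id")),
    features
  )
  readr::write_csv(features, file.path(out, "features.csv"), progress = FALSE)

  envelopes <- stage("icp", build_envelopes(purrr::map(train, "curve"),
                                            purrr::map_chr(train, "label")))
  readr::write_csv(envelopes, file.path(out, "envelopes.csv"), progress = FALSE)

  inform("Training elastic-net classifier...")
  model <- stage("train", fit_elastic_net(
    features, purrr::map_chr(train, "label"),
    alpha = config$alpha, n_folds = config$n_folds, seed = config$seed,
    threshold = config$threshold
  ))
  save_model(model, file.path(out, "model.json"))

  inform("Simulating assessment cohort...")
  assess_seed <- as.integer((config$seed + 10000) %% (2^31 - 1))
  assess_cohort <- stage("simulate", simulate_cohort(
    n_normal = config$assess$n_normal, n_abnormal = config$assess$n_abnormal,
    seed = assess_seed, duration_s = config$duration_s, fs = config$fs
  ))
  assess_cohort$subject_id <- paste0("assess_", assess_cohort$subject_id)
  assess <- stage("analyze", analyse_cohort(assess_cohort, "assess"))

  inform("Predicting and assembling reports...")
  assess_features <- dplyr::bind_rows(purrr::map(assess, "features"))
  predictions <- dplyr::bind_cols(
    tibble::tibble(subject_id = purrr::map_chr(assess, "subject_id")),
    stage("predict", predict(model, assess_features))
  )
  readr::write_csv(predictions, file.path(out, "predictions.csv"),
                   progress = FALSE)

  ages <- withr::with_seed(assess_seed, round(runif(nrow(assess_cohort), 6, 17)))
  vitals <- purrr::imap_dfr(assess, function(a, i) {
    simulate_vitals(a$label, age_years = ages[i],
                    seed = assess_seed + i, subject_id = a$subject_id)
  })
  write_vitals(vitals, file.path(out, "vitals.json"))

  reports <- stage("report", dplyr::bind_rows(purrr::imap(assess, function(a, i) {
    build_report(
      a$indices,
      vitals = vitals[i, ],
      verdict = predictions$label[i],
      refs = refs,
      age_years = ages[i],
      subject_id = a$subject_id
    )
  })))
  write_reports(reports, file.path(out, "reports.json"),
                csv_path = file.path(out, "reports.csv"))

  invisible(list(model = model, features = features,
                 predictions = predictions, reports = reports,
                 envelopes = envelopes, out_dir = out, config = config))
}
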