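#' Fit the elastic-net logistic classifier on ICP features
#'
#' Trains a penalized logistic regression
#' `logit P(abnormal) = beta0 + x' beta` on ICP feature vectors, with the
#' elastic-net penalty mixing L1 and L2 at `alpha`. The penalty weight
#' `lambda` is chosen by seeded stratified k-fold cross-validation under
#' misclassification loss: for every lambda on the glmnet path the held-out
#' error is averaged over folds, and the selected lambda is either the
#' largest one whose mean error is within one standard error of the minimum
#' (`rule = "1se"`, the default, matching the usual CV-curve reading) or the
#' largest lambda attaining the minimum (`rule = "min"`). The model is then
#' refit on all data at the selected lambda.
#'
#' Features are standardized internally before penalization; coefficients
#' are reported on the original percentage scale. The class encoding is
#' `abnormal = 1`.
#'
#' @param features A data frame whose numeric `phi_*` columns are the ICP
#'   predictor values (rows = subjects), e.g. `bind_rows()` of
#'   [icp_features()] outputs; any non-`phi_` columns are ignored.
#' @param labels Character/factor vector in `{"normal", "abnormal"}`.
#' @param alpha Elastic-net mixing in \[0, 1\]; 1 is the lasso, 0 ridge.
#' @param n_folds Number of CV folds (stratified within class).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional decreasing lambda grid; default lets glmnet build
#'   its path on the full data.
#' @param rule Lambda selection rule, `"1se"` or `"min"`.
#' @param threshold Posterior-probability cut for the abnormal label.
#' @param ... Additional arguments forwarded to [glmnet::glmnet()], e.g. a
#'   tighter convergence threshold `thresh`.
#'
#' @return A `taa_enet` object: list with `beta0`, `betas` (named by
#'   feature), `alpha`, `lambda_selected`, `feature_grid_deg`, `cv_curve`
#'   (tibble: `lambda`, `error_mean`, `error_se`, `nzero`), `threshold`,
#'   `rule`, `seed`. Supports `predict()`, `tidy()`, `glance()`,
#'   `autoplot()`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_normal = 5, n_abnormal = 5, seed = 1,
#'                           duration_s = 120)
#' feats <- dplyr::bind_rows(lapply(cohort$recording, function(r)
#'   icp_features(compute_icp(compute_indices(r)))))
#' fit <- fit_elastic_net(feats, cohort$label, seed = 1, n_folds = 5)
#' glance(fit)
#' }
#' @export
fit_elastic_net <- function(features, labels, alpha = 0.5, n_folds = 10,
                            seed = 1, lambda = NULL,
                            rule = c("1se", "min"), threshold = 0.5, ...) {
  rule <- match.arg(rule)
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  X <- feature_matrix(features)
  y <- encode_labels(labels)
  if (nrow(X) != length(y)) abort("`features` and `labels` lengths differ.")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < 2)) {
    abort("Need at least 2 samples of each class to fit the classifier.")
  }
  if (anyNA(X)) abort("Missing values in the feature matrix.")
  if (n_folds > min(counts)) {
    abort(sprintf(
      "Cannot build %d stratified folds with only %d samples in the smaller class.",
      n_folds, min(counts)))
  }

    # extra arguments (e.g. a tighter `thresh`) forwarded to glmnet
  # small folds trip glmnet's class-size caution; expected at cohort scale
  quiet_glmnet <- function(...) {
    withCallingHandlers(
      glmnet::glmnet(...),
      warning = function(w) {
        if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  full <- quiet_glmnet(X, y, family = "binomial", alpha = alpha,
                       lambda = lambda, standardize = TRUE, ...)
  lambda_seq <- full$lambda

  foldid <- withr::with_seed(seed, stratified_folds(y, n_folds))
  fold_err <- matrix(NA_real_, nrow = n_folds, ncol = length(lambda_seq))
  for (k in seq_len(n_folds)) {
    tr <- foldid != k
    fit_k <- quiet_glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = alpha, lambda = lambda_seq,
                          standardize = TRUE, ...)
    p <- predict(fit_k, X[!tr, , drop = FALSE], s = lambda_seq,
                 type = "response")
    pred <- p >= 0.5
    fold_err[k, ] <- colMeans(pred != matrix(y[!tr], nrow = sum(!tr),
                                             ncol = ncol(pred)))
  }
  err_mean <- colMeans(fold_err)
  err_se <- apply(fold_err, 2, sd) / sqrt(n_folds)

  i_min <- which(err_mean == min(err_mean))[1]  # lambda_seq decreasing: first = largest
  i_sel <- if (rule == "min") {
    i_min
  } else {
    which(err_mean <= err_mean[i_min] + err_se[i_min])[1]
  }
  lambda_selected <- lambda_seq[i_sel]

  cf <- as.numeric(coef(full, s = lambda_selected))
  betas <- cf[-1]
  names(betas) <- colnames(X)

  structure(
    list(
      beta0 = cf[1],
      betas = betas,
      alpha = alpha,
      lambda_selected = lambda_selected,
      feature_grid_deg = as.numeric(sub("^phi_", "", colnames(X))),
      cv_curve = tibble::tibble(
        lambda = lambda_seq,
        error_mean = err_mean,
        error_se = err_se,
        nzero = as.integer(full$df)
      ),
      threshold = threshold,
      rule = rule,
      seed = seed,
      n_folds = n_folds
    ),
    class = "taa_enet"
  )
}

# features tibble/matrix -> numeric matrix of phi_* columns
feature_matrix <- function(features) {
  if (is.matrix(features)) {
    if (is.null(colnames(features))) {
      abort("A feature matrix needs `phi_<angle>` column names.")
    }
    return(features)
  }
  cols <- grep("^phi_", names(features), value = TRUE)
  if (length(cols) == 0) abort("No `phi_*` feature columns found.")
  as.matrix(features[cols])
}

encode_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("normal", "abnormal"))
  if (length(bad) > 0) {
    abort(paste0("Unknown label(s): ", paste(bad, collapse = ", "),
                 "; expected 'normal' or 'abnormal'."))
  }
  as.integer(labels == "abnormal")
}

# stratified fold ids: balanced assignment within each class
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Predict normal/abnormal breathing from ICP features
#'
#' @param object A `taa_enet` model.
#' @param new_features A data frame with the model's `phi_*` columns, a
#'   named numeric vector, or a bare numeric vector in feature-grid order.
#' @param ... Unused.
#' @return A tibble with one row per subject: `probability` (of abnormal
#'   breathing) and `label`.
#' @export
predict.taa_enet <- function(object, new_features, ...) {
  if (is.numeric(new_features) && is.null(dim(new_features))) {
    new_features <- matrix(new_features, nrow = 1,
                           dimnames = list(NULL, names(object$betas)))
  }
  X <- feature_matrix(new_features)
  missing_cols <- setdiff(names(object$betas), colnames(X))
  if (length(missing_cols) > 0 || ncol(X) != length(object$betas)) {
    abort("Feature columns do not match the model's feature grid.")
  }
  X <- X[, names(object$betas), drop = FALSE]
  score <- drop(object$beta0 + X %*% object$betas)
  prob <- plogis(score)
  tibble::tibble(
    probability = unname(prob),
    label = ifelse(prob >= object$threshold, "abnormal", "normal")
  )
}

#' Evaluate a fitted classifier on labelled features
#'
#' @param model A `taa_enet` model.
#' @param features Feature rows as in [predict.taa_enet()].
#' @param labels True labels, `"normal"`/`"abnormal"`.
#' @return A one-row tibble of confusion counts (abnormal = positive class)
#'   and accuracy: `n`, `tp`, `tn`, `fp`, `fn`, `accuracy`.
#' @export
evaluate_classifier <- function(model, features, labels) {
  y <- encode_labels(labels)
  if (length(y) == 0) abort("Empty evaluation set.")
  pred <- encode_labels(predict(model, features)$label)
  tibble::tibble(
    n = length(y),
    tp = sum(pred == 1 & y == 1),
    tn = sum(pred == 0 & y == 0),
    fp = sum(pred == 1 & y == 0),
    fn = sum(pred == 0 & y == 1),
    accuracy = mean(pred == y)
  )
}

#' @exportS3Method generics::tidy
tidy.taa_enet <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$betas)),
    angle_deg = c(NA_real_, x$feature_grid_deg),
    estimate = c(x$beta0, unname(x$betas))
  )
}

#' @exportS3Method generics::glance
glance.taa_enet <- function(x, ...) {
  i <- which(x$cv_curve$lambda == x$lambda_selected)[1]
  tibble::tibble(
    alpha = x$alpha,
    lambda_selected = x$lambda_selected,
    rule = x$rule,
    cv_error = x$cv_curve$error_mean[i],
    cv_error_se = x$cv_curve$error_se[i],
    n_nonzero = sum(x$betas != 0),
    n_folds = x$n_folds,
    threshold = x$threshold
  )
}

#' @export
print.taa_enet <- function(x, ...) {
  g <- glance(x)
  cat("Elastic-net TAA classifier\n")
  cat(sprintf("  alpha = %.2f, lambda = %.5g (%s rule), CV error = %.3f (SE %.3f)\n",
              g$alpha, g$lambda_selected, g$rule, g$cv_error, g$cv_error_se))
  cat(sprintf("  %d of %d coefficients nonzero; threshold = %.2f\n",
              g$n_nonzero, length(x$betas), g$threshold))
  invisible(x)
}

#' Persist a fitted classifier as JSON
#'
#' Coefficients are written at full double precision so that a load
#' reproduces the model bit-for-bit.
#'
#' @param model A `taa_enet` model.
#' @param path JSON path.
#' @return `save_model()` invisibly returns `path`; `load_model()` the
#'   restored `taa_enet` object.
#' @export
save_model <- function(model, path) {
  payload <- list(
    version = 1L,
    beta0 = model$beta0,
    betas = as.list(model$betas),
    alpha = model$alpha,
    lambda_selected = model$lambda_selected,
    feature_grid_deg = model$feature_grid_deg,
    cv_curve = model$cv_curve,
    threshold = model$threshold,
    rule = model$rule,
    seed = model$seed,
    n_folds = model$n_folds
  )
  # I(17): 17 significant digits, enough for an exact double round-trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(paste0("Corrupt model file: ",
                                                   conditionMessage(e))))
  required <- c("beta0", "betas", "alpha", "lambda_selected",
                "feature_grid_deg", "cv_curve", "threshold")
  missing_f <- setdiff(required, names(raw))
  if (length(missing_f) > 0) {
    abort(paste0("Model file is missing field(s): ",
                 paste(missing_f, collapse = ", "), "."),
          class = "ripasync_schema_error")
  }
  betas <- unlist(raw$betas)
  structure(
    list(
      beta0 = raw$beta0,
      betas = betas,
      alpha = raw$alpha,
      lambda_selected = raw$lambda_selected,
      feature_grid_deg = as.numeric(raw$feature_grid_deg),
      cv_curve = tibble::as_tibble(raw$cv_curve),
      threshold = raw$threshold,
      rule = raw$rule %||% "1se",
      seed = raw$seed %||% NA_integer_,
      n_folds = raw$n_folds %||% NA_integer_
    ),
    class = "taa_enet"
  )
}
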