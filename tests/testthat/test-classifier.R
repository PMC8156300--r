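# small helper cohorts for classifier tests (recordings kept short: the
# phase separation, not the recording length, is what matters here)
small_cohort <- function(seed) {
  simulate_cohort(n_normal = 5, n_abnormal = 5, seed = seed, duration_s = 90)
}

test_that("fit + predict separate the synthetic conditions", {
  train <- small_cohort(21)
  feats <- cohort_features(train, window_s = 30, step_s = 10)
  fit <- fit_elastic_net(feats, train$label, n_folds = 5, seed = 1)

  test <- small_cohort(22)
  tf <- cohort_features(test, window_s = 30, step_s = 10)
  ev <- evaluate_classifier(fit, tf, test$label)
  expect_identical(ev$n, 10L)
  expect_equal(ev$accuracy, 1)
  expect_identical(ev$tp + ev$fn, 5L)

  # a fully synchronous subject is called normal
  sync <- icp_features(compute_icp(rep(0, 30)))
  expect_identical(predict(fit, sync)$label, "normal")
})

test_that("fitting is deterministic given the seed", {
  train <- small_cohort(23)
  feats <- cohort_features(train, window_s = 30, step_s = 10)
  f1 <- fit_elastic_net(feats, train$label, n_folds = 5, seed = 42)
  f2 <- fit_elastic_net(feats, train$label, n_folds = 5, seed = 42)
  expect_identical(f1$lambda_selected, f2$lambda_selected)
  expect_identical(f1$betas, f2$betas)
  expect_identical(f1$cv_curve, f2$cv_curve)
})

test_that("shrinkage behaves along the lambda path", {
  train <- small_cohort(24)
  feats <- cohort_features(train, window_s = 30, step_s = 10)
  fit <- fit_elastic_net(feats, train$label, n_folds = 5, seed = 3)
  # nonzero-coefficient count and L1 norm non-increasing as lambda grows
  cv <- fit$cv_curve[order(fit$cv_curve$lambda), ]
  expect_true(all(diff(cv$nzero) <= 0))
  X <- as.matrix(dplyr::select(feats, dplyr::starts_with("phi_")))
  y <- as.integer(train$label == "abnormal")
  path <- suppressWarnings(glmnet::glmnet(X, y, family = "binomial", alpha = 0.5))
  l1 <- apply(abs(path$beta), 2, sum)  # columns ordered by decreasing lambda
  expect_true(all(diff(l1) >= -1e-8))

  # at very large lambda everything shrinks to the majority-class intercept
  big <- fit_elastic_net(feats, train$label, n_folds = 5, seed = 3,
                         lambda = c(1e4, 1e3), rule = "min")
  expect_true(all(big$betas == 0))
  p <- predict(big, feats)
  expect_identical(length(unique(p$label)), 1L)
})

test_that("unpenalized fit matches the IRLS oracle at lambda = 0, p = 2", {
  # two well-separated but overlapping Gaussian classes: finite MLE
  withr::local_seed(77)
  n <- 60
  X <- rbind(
    cbind(rnorm(n, 0, 1.2), rnorm(n, 0, 1.2)),
    cbind(rnorm(n, 2.2, 1.2), rnorm(n, 2.2, 1.2))
  )
  colnames(X) <- c("phi_0", "phi_5")
  y <- c(rep(0, n), rep(1, n))
  labels <- ifelse(y == 1, "abnormal", "normal")
  lambda_grid <- c(10^seq(1, -4, length.out = 40), 0)
  fit <- fit_elastic_net(tibble::as_tibble(X), labels, alpha = 0.5,
                         n_folds = 5, seed = 1, lambda = lambda_grid,
                         rule = "min")
  oracle <- irls_logistic(X, y)
  cf <- as.numeric(coef(glmnet::glmnet(X, y, family = "binomial", alpha = 0.5,
                                       lambda = lambda_grid,
                                       thresh = 1e-14), s = 0))
  expect_equal(cf, unname(oracle), tolerance = 1e-4)
  # the package's fit constrained to lambda 0 agrees with the oracle too
  refit <- fit_elastic_net(tibble::as_tibble(X), labels, alpha = 0.5,
                           n_folds = 5, seed = 1,
                           lambda = 0, rule = "min", thresh = 1e-12)
  expect_equal(unname(c(refit$beta0, refit$betas)), unname(oracle),
               tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  train <- small_cohort(25)
  feats <- cohort_features(train, window_s = 30, step_s = 10)
  expect_error(fit_elastic_net(feats, rep("normal", 10)), "each class")
  expect_error(fit_elastic_net(feats, train$label, n_folds = 10, seed = 1),
               "stratified")
  expect_error(fit_elastic_net(feats[1:3, ], train$label), "lengths differ")
  bad <- feats
  bad$phi_0[1] <- NA
  expect_error(fit_elastic_net(bad, train$label, n_folds = 5), "Missing values")
  expect_error(fit_elastic_net(feats, train$label, alpha = 2, n_folds = 5),
               "alpha")
  fit <- fit_elastic_net(feats, train$label, n_folds = 5, seed = 1)
  expect_error(predict(fit, feats[, 1:10]), "feature grid")
  expect_error(evaluate_classifier(fit, feats[0, ], character(0)), "Empty")
})

test_that("the null model predicts 0.5 and tidy/glance expose the fit", {
  train <- small_cohort(26)
  feats <- cohort_features(train, window_s = 30, step_s = 10)
  fit <- fit_elastic_net(feats, train$label, n_folds = 5, seed = 1)
  null_fit <- fit
  null_fit$betas[] <- 0
  null_fit$beta0 <- 0
  p <- predict(null_fit, feats[1, ])
  expect_equal(p$probability, 0.5)

  td <- tidy(fit)
  expect_identical(nrow(td), 38L)  # intercept + 37 grid angles
  expect_identical(td$term[1], "(Intercept)")
  g <- glance(fit)
  expect_true(g$lambda_selected %in% fit$cv_curve$lambda)
  expect_identical(g$n_nonzero, sum(fit$betas != 0))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("model JSON round-trips bit-equal and rejects damage", {
  train <- small_cohort(27)
  feats <- cohort_features(train, window_s = 30, step_s = 10)
  fit <- fit_elastic_net(feats, train$label, n_folds = 5, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(fit, f)
  back <- load_model(f)
  expect_identical(back$beta0, fit$beta0)
  expect_identical(back$betas, fit$betas)
  expect_identical(back$lambda_selected, fit$lambda_selected)
  expect_equal(as.data.frame(back$cv_curve), as.data.frame(fit$cv_curve))
  expect_identical(predict(back, feats), predict(fit, feats))

  writeLines("{not json", f)
  expect_error(load_model(f), "Corrupt")
  jsonlite::write_json(list(beta0 = 1), f, auto_unbox = TRUE)
  expect_error(load_model(f), class = "ripasync_schema_error")
  expect_error(load_model(tempfile()), "No such file")
})
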