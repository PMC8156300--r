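# Independent oracles used by the tests; deliberately simple and separate
# from the package implementation.

# Unpenalized logistic regression by Newton/IRLS on raw (unstandardized)
# predictors with an intercept.
irls_logistic <- function(X, y, max_iter = 200, tol = 1e-12) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (i in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X1, w * X1), crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

# Brute-force survival-function counts on the integer degree grid.
icp_oracle <- function(phase) {
  vapply(0:180, function(th) 100 * sum(phase >= th) / length(phase), numeric(1))
}

# Shoelace area of a closed polygon.
shoelace_area <- function(x, y) {
  0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}

# ICP features of a recording, as used throughout the pipeline tests.
features_of <- function(rec, window_s = 30, step_s = 5) {
  icp_features(compute_icp(compute_indices(rec, window_s, step_s)))
}

cohort_features <- function(cohort, window_s = 30, step_s = 5) {
  dplyr::bind_rows(lapply(cohort$recording, features_of,
                          window_s = window_s, step_s = step_s))
}
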