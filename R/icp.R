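icp_grid <- function() 0:180

#' Inverse cumulative percentage (ICP) curve of a phase series
#'
#' The ICP summarises the distribution of the per-window phase difference as
#' a survival curve on an integer-degree grid: for each angle theta in
#' 0–180°, the percentage of windows whose phase is at or above theta. It
#' always starts at 100% and is non-increasing, so a curve hugging the left
#' edge means consistently synchronous breathing while mass at high angles
#' means sustained asynchrony — and, unlike the mean phase, it is robust to
#' outliers and reveals bimodal patterns.
#'
#' The median and quartile markers are read off the curve with a
#' deterministic tie rule: the marker for percentile `p` is the largest grid
#' angle whose ICP still *exceeds* `100 - p` (e.g. the median is the largest
#' theta with ICP > 50%). On integer-valued phase series this equals the
#' inverse-empirical-CDF (type 1) order statistic.
#'
#' @param x A numeric vector of phase magnitudes in degrees, or a
#'   `taa_indices` tibble (its `phase_deg` column is used).
#'
#' @return A `taa_icp` tibble with columns `theta_deg`, `icp_pct` and
#'   attributes `median_deg`, `q25_deg`, `q75_deg` (see `glance()`).
#' @examples
#' curve <- compute_icp(c(10, 20, 30, 40))
#' glance(curve)
#' @export
compute_icp <- function(x) {
  phase <- if (is.data.frame(x)) x$phase_deg else x
  if (is.null(phase) || length(phase) == 0) {
    abort("Phase series is empty; cannot build an ICP curve.")
  }
  if (anyNA(phase)) abort("Phase series contains missing values.")
  if (any(phase < 0 | phase > 180)) {
    abort("Phase magnitudes must lie in [0, 180] degrees.")
  }
  grid <- icp_grid()
  n <- length(phase)
  icp <- vapply(grid, function(th) 100 * sum(phase >= th) / n, numeric(1))
  marker <- function(p) {
    ok <- icp > (100 - p)
    grid[max(which(ok))]
  }
  structure(
    tibble::tibble(theta_deg = grid, icp_pct = icp),
    median_deg = marker(50),
    q25_deg = marker(25),
    q75_deg = marker(75),
    n_windows = length(phase),
    class = c("taa_icp", class(tibble::tibble()))
  )
}

#' @exportS3Method generics::glance
glance.taa_icp <- function(x, ...) {
  tibble::tibble(
    median_deg = attr(x, "median_deg"),
    q25_deg = attr(x, "q25_deg"),
    q75_deg = attr(x, "q75_deg"),
    n_windows = attr(x, "n_windows")
  )
}

#' Reference envelopes of labelled ICP curves
#'
#' Given a labelled cohort of ICP curves, computes the pointwise band each
#' class occupies at every grid angle — by default the min–max range, or
#' central percentile bands via `method = "quantile"`. These are the shaded
#' normal/abnormal regions a new subject's curve is displayed against.
#'
#' @param curves A list of `taa_icp` curves (e.g. a list-column).
#' @param labels Character vector, `"normal"`/`"abnormal"`, one per curve.
#' @param method `"range"` (pointwise min–max) or `"quantile"`.
#' @param probs Lower/upper probabilities for `method = "quantile"`.
#'
#' @return A tibble with columns `theta_deg`, `normal_lo`, `normal_hi`,
#'   `abnormal_lo`, `abnormal_hi`.
#' @export
build_envelopes <- function(curves, labels, method = c("range", "quantile"),
                            probs = c(0.05, 0.95)) {
  method <- match.arg(method)
  labels <- as.character(labels)
  if (length(curves) != length(labels)) {
    abort("`curves` and `labels` must have the same length.")
  }
  for (cls in c("normal", "abnormal")) {
    if (!any(labels == cls)) {
      abort(paste0("No curve labelled '", cls, "'; both classes are required."))
    }
  }
  band <- function(cls) {
    mat <- do.call(cbind, purrr::map(curves[labels == cls], "icp_pct"))
    if (method == "range") {
      list(lo = apply(mat, 1, min), hi = apply(mat, 1, max))
    } else {
      list(lo = apply(mat, 1, quantile, probs = probs[1], names = FALSE),
           hi = apply(mat, 1, quantile, probs = probs[2], names = FALSE))
    }
  }
  nb <- band("normal")
  ab <- band("abnormal")
  tibble::tibble(
    theta_deg = icp_grid(),
    normal_lo = nb$lo, normal_hi = nb$hi,
    abnormal_lo = ab$lo, abnormal_hi = ab$hi
  )
}

#' ICP feature vector for classification
#'
#' Samples the ICP curve on a fixed coarse angle grid (default every 5°,
#' giving 37 predictors) in fixed order; these are the predictor values the
#' elastic-net classifier consumes. Returned as a one-row tibble with columns
#' `phi_0`, `phi_5`, ..., so cohort feature matrices are built with
#' `dplyr::bind_rows()`.
#'
#' @param curve A `taa_icp` curve.
#' @param feature_grid_deg Angles (subset of 0–180) at which to sample.
#' @return A one-row tibble of ICP percentages named `phi_<angle>`.
#' @export
icp_features <- function(curve, feature_grid_deg = seq(0, 180, by = 5)) {
  if (any(feature_grid_deg < 0 | feature_grid_deg > 180)) {
    abort("Feature grid angles must lie in [0, 180].")
  }
  vals <- curve$icp_pct[match(feature_grid_deg, curve$theta_deg)]
  if (anyNA(vals)) abort("Feature grid angles must lie on the integer ICP grid.")
  names(vals) <- paste0("phi_", feature_grid_deg)
  tibble::as_tibble(as.list(vals))
}

# feature-grid angles encoded in a feature tibble's column names
feature_grid_of <- function(features) {
  cols <- grep("^phi_", names(features), value = TRUE)
  as.numeric(sub("^phi_", "", cols))
}

#' Plot-ready table for an ICP display
#'
#' Joins a subject's curve, its median/quartile markers and (optionally) the
#' cohort reference envelopes into one long table for rendering; no values
#' are computed beyond the join. `autoplot()` on a `taa_icp` object uses it.
#'
#' @param curve A `taa_icp` curve.
#' @param envelope Optional envelope table from [build_envelopes()].
#' @return A tibble with columns `theta_deg`, `icp_pct`, `part` (`"curve"`
#'   or `"marker"`), `marker` (`"median"`, `"q25"`, `"q75"` or `NA`) plus the
#'   envelope columns when supplied.
#' @export
icp_plot_data <- function(curve, envelope = NULL) {
  g <- glance(curve)
  markers <- tibble::tibble(
    theta_deg = c(g$median_deg, g$q25_deg, g$q75_deg),
    icp_pct = curve$icp_pct[match(c(g$median_deg, g$q25_deg, g$q75_deg),
                                  curve$theta_deg)],
    part = "marker",
    marker = c("median", "q25", "q75")
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(curve), part = "curve", marker = NA_character_),
    markers
  )
  if (!is.null(envelope)) {
    out <- dplyr::left_join(out, envelope, by = "theta_deg")
  }
  out
}

#' Serialize ICP curves and envelopes as CSV
#'
#' @param curve A `taa_icp` curve.
#' @param path CSV path (`theta_deg,icp_pct`); a `<path>.meta.json` sidecar
#'   stores the median/quartile markers.
#' @return Invisibly, `path`.
#' @export
write_icp <- function(curve, path) {
  readr::write_csv(tibble::as_tibble(curve), path, progress = FALSE)
  jsonlite::write_json(as.list(glance(curve)), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_icp
#' @export
read_icp <- function(path) {
  df <- readr::read_csv(path, col_types = "dd", progress = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(
    df,
    median_deg = meta$median_deg %||% NA_real_,
    q25_deg = meta$q25_deg %||% NA_real_,
    q75_deg = meta$q75_deg %||% NA_real_,
    n_windows = meta$n_windows %||% NA_integer_,
    class = c("taa_icp", class(tibble::tibble()))
  )
}
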