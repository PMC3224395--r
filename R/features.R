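#' Waveform length of a signal window
#'
#' Sum of absolute successive sample differences,
#' \deqn{WL = \sum_{r=2}^{N} |t_r - t_{r-1}|,}
#' a standard measure of waveform complexity/amplitude variation in
#' myoelectric pattern recognition.
#'
#' @param samples Numeric vector of at least 2 samples.
#' @return Non-negative scalar.
#' @examples
#' waveform_length(c(0, 1, 0, 1)) # 3
#' @export
waveform_length <- function(samples) {
  if (length(samples) < 2) stop("waveform length requires at least 2 samples")
  sum(abs(diff(samples)))
}

#' Root mean square amplitude of a signal window
#'
#' \deqn{RMS = \sqrt{(m_1^2 + \dots + m_n^2)/n}}
#' summarizing signal amplitude over the window (n = 256 samples in the
#' default pipeline).
#'
#' @param samples Non-empty numeric vector.
#' @return Non-negative scalar.
#' @export
rms_amplitude <- function(samples) {
  if (length(samples) < 1) stop("rms requires a non-empty input")
  sqrt(mean(samples^2))
}

#' Autoregressive model coefficients of a signal window
#'
#' Fits the AR(p) model \eqn{t_n = \sum_{i=1}^p q_i t_{n-i} + w_n} and
#' returns the coefficient estimates in prediction form (positive `q1`
#' for positively lag-1-correlated signals). The default estimator is
#' Burg's method, which is stable on short EMG windows; Yule-Walker is
#' available for sensitivity checks.
#'
#' @param samples Numeric vector, longer than `order`, non-constant.
#' @param order Model order p (default 4).
#' @param method `"burg"` or `"yule_walker"`.
#' @return Numeric vector `q_1..q_p`.
#' @examples
#' x <- simulate_ar_process(c(0.9), n = 2048, seed = 1)
#' ar_coefficients(x, order = 1)
#' @export
ar_coefficients <- function(samples, order = 4L, method = c("burg", "yule_walker")) {
  method <- match.arg(method)
  stopifnot(order >= 1)
  if (length(samples) <= order) stop("need more samples than the AR order")
  if (stats::var(samples) == 0) stop("AR coefficients undefined for a constant (zero-variance) signal")
  fit <- tryCatch(
    switch(method,
      burg = stats::ar.burg(samples, aic = FALSE, order.max = order, demean = TRUE),
      yule_walker = stats::ar.yw(samples, aic = FALSE, order.max = order, demean = TRUE)
    ),
    error = function(e) stop("AR estimation failed (singular autocovariance?): ", conditionMessage(e))
  )
  q <- as.numeric(fit$ar)
  if (length(q) != order || any(!is.finite(q))) {
    stop("AR estimation returned non-finite or wrong-order coefficients")
  }
  q
}

#' Extract the 24-dimensional feature table from labelled windows
#'
#' Computes six features per channel — waveform length, RMS and four AR
#' coefficients — for each window, in fixed channel order (ED, PL, FCU,
#' ECR), giving 24 features per window. Feature columns are named
#' `<channel>_<feature>` (`ED_wl`, `ED_rms`, `ED_ar1` ... `ECR_ar4`).
#'
#' @param segments A labelled `semg_segments` (see [assign_labels()]).
#' @param ar_order AR model order (default 4).
#' @param ar_method AR estimator, `"burg"` (default) or `"yule_walker"`.
#' @return A data.frame with columns `subject_id`, `window_index`,
#'   `label` and the 24 feature columns; one row per window.
#' @export
extract_features <- function(segments, ar_order = 4L, ar_method = "burg") {
  stopifnot(inherits(segments, "semg_segments"))
  if (is.null(segments$labels)) stop("segments must be labelled first (see assign_labels)")
  n <- n_segments(segments)
  muscles <- names(segments$data)
  cols <- list()
  for (m in muscles) {
    mat <- segments$data[[m]]
    wl <- rowSums(abs(mat[, -1, drop = FALSE] - mat[, -ncol(mat), drop = FALSE]))
    rms <- sqrt(rowMeans(mat^2))
    ar <- matrix(NA_real_, n, ar_order)
    for (k in seq_len(n)) {
      ar[k, ] <- tryCatch(
        ar_coefficients(mat[k, ], order = ar_order, method = ar_method),
        error = function(e) {
          stop(sprintf("channel %s, window %d: %s", m, segments$window_index[k], conditionMessage(e)))
        }
      )
    }
    cols[[paste0(m, "_wl")]] <- wl
    cols[[paste0(m, "_rms")]] <- rms
    for (j in seq_len(ar_order)) cols[[paste0(m, "_ar", j)]] <- ar[, j]
  }
  out <- data.frame(
    subject_id = rep(segments$subject_id, n),
    window_index = segments$window_index,
    label = as.integer(segments$labels),
    cols,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Names of the feature columns in a feature table, in canonical order.
feature_column_names <- function(ar_order = 4L, muscles = MUSCLES) {
  unlist(lapply(muscles, function(m) {
    c(paste0(m, "_wl"), paste0(m, "_rms"), paste0(m, "_ar", seq_len(ar_order)))
  }))
}

# Split a feature table into its feature matrix and metadata.
feature_matrix <- function(features, feature_names = NULL) {
  feature_names <- feature_names %||% setdiff(
    names(features), c("subject_id", "window_index", "label")
  )
  missing <- setdiff(feature_names, names(features))
  if (length(missing)) {
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  }
  as.matrix(features[, feature_names, drop = FALSE])
}
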