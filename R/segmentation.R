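#' Window length and step in samples
#'
#' Converts a window/step specification in milliseconds to sample counts at
#' a given sampling rate. The pipeline default (250 ms window, 125 ms step
#' at 1024 Hz) gives 256-sample windows advanced by 128 samples, i.e. 50%
#' overlap.
#'
#' @param fs Sampling rate, samples/s.
#' @param window_ms Window length, milliseconds.
#' @param step_ms Step between consecutive window starts, milliseconds.
#' @return Named integer vector `c(window_samples, step_samples)`.
#' @examples
#' window_params(1024, 250, 125) # 256, 128
#' @export
window_params <- function(fs, window_ms = 250, step_ms = 125) {
  stopifnot(fs > 0, window_ms > 0, step_ms > 0)
  w <- as.integer(round(fs * window_ms / 1000))
  s <- as.integer(round(fs * step_ms / 1000))
  if (s > w) warning("step exceeds window length: windows will not overlap and will leave gaps")
  c(window_samples = w, step_samples = s)
}

#' Cut a recording into overlapping fixed-length windows
#'
#' Window `k` (1-based index) covers samples `[(k-1)*step, (k-1)*step +
#' window)` (0-based, half-open). Trailing samples that do not fill a
#' window are discarded. For a recording of length `L >= window` the
#' number of windows is `floor((L - window) / step) + 1`; shorter
#' recordings yield zero windows.
#'
#' @param recording A `semg_recording` (or any list with a `channels`
#'   matrix, `labels`, `fs` and a `subject` with `subject_id`).
#' @param window_samples,step_samples Window geometry in samples, e.g.
#'   from [window_params()].
#' @return A `semg_segments` object: per-muscle matrices of dimension
#'   n_windows x window_samples, window start offsets, window indices and
#'   (after [assign_labels()]) one class label per window.
#' @export
segment_recording <- function(recording, window_samples = 256L, step_samples = 128L) {
  stopifnot(window_samples >= 1, step_samples >= 1)
  ch <- recording$channels
  L <- nrow(ch)
  n_win <- if (L >= window_samples) {
    (L - window_samples) %/% step_samples + 1L
  } else {
    0L
  }
  starts <- (seq_len(n_win) - 1L) * step_samples # 0-based
  sample_idx <- outer(starts, seq_len(window_samples), `+`) # n_win x window
  data <- lapply(stats::setNames(colnames(ch), colnames(ch)), function(m) {
    matrix(ch[as.vector(sample_idx), m], nrow = n_win, ncol = window_samples)
  })
  structure(
    list(
      window_samples = as.integer(window_samples),
      step_samples = as.integer(step_samples),
      starts = as.integer(starts),
      window_index = seq_len(n_win),
      data = data,
      labels = NULL,
      subject_id = recording$subject$subject_id %||% NA_character_,
      fs = recording$fs
    ),
    class = "semg_segments"
  )
}

#' Assign one class label per window
#'
#' Labels each window from the per-sample label track. Under policy
#' `"pure"`, windows whose span contains more than one distinct label are
#' dropped (clean class exemplars for training). Under `"majority"` every
#' window is kept and labelled with its modal per-sample label; exact ties
#' are broken toward the label that starts earlier within the window
#' (useful for contiguous predicted-class traces over a whole recording).
#'
#' @param segments A `semg_segments` from [segment_recording()].
#' @param label_track Integer per-sample class labels covering the
#'   segmented span.
#' @param policy `"pure"` or `"majority"`.
#' @return The `semg_segments` object with `labels` set (and, under
#'   `"pure"`, mixed windows removed).
#' @export
assign_labels <- function(segments, label_track, policy = c("pure", "majority")) {
  policy <- match.arg(policy)
  stopifnot(inherits(segments, "semg_segments"))
  n_win <- length(segments$starts)
  w <- segments$window_samples
  if (n_win > 0 && length(label_track) < max(segments$starts) + w) {
    stop("label track does not cover all segment spans")
  }
  labs <- integer(n_win)
  keep <- rep(TRUE, n_win)
  for (k in seq_len(n_win)) {
    span <- label_track[(segments$starts[k] + 1L):(segments$starts[k] + w)]
    u <- unique(span)
    if (length(u) == 1L) {
      labs[k] <- u
    } else if (policy == "pure") {
      keep[k] <- FALSE
    } else {
      counts <- table(span)
      top <- as.integer(names(counts)[counts == max(counts)])
      if (length(top) == 1L) {
        labs[k] <- top
      } else {
        # tie: earliest-starting label within the window wins
        first_pos <- vapply(top, function(l) match(l, span), integer(1))
        labs[k] <- top[which.min(first_pos)]
      }
    }
  }
  segments$labels <- labs
  if (policy == "pure" && !all(keep)) {
    segments <- subset_segments(segments, which(keep))
  }
  segments
}

# Keep only the windows in `idx` (preserving original window indices).
subset_segments <- function(segments, idx) {
  segments$starts <- segments$starts[idx]
  segments$window_index <- segments$window_index[idx]
  segments$data <- lapply(segments$data, function(m) m[idx, , drop = FALSE])
  if (!is.null(segments$labels)) segments$labels <- segments$labels[idx]
  segments
}

#' Thin labelled windows to a fixed budget, stratified by class
#'
#' Selects up to `n_max` windows, allocating the budget across the classes
#' present proportionally to their counts (largest-remainder rule) and
#' picking evenly spaced windows within each class. Used by the pipeline
#' to emulate extracting a fixed amount of data per protocol (the default
#' budget of 47 windows corresponds to 6 s of signal at the default
#' 250 ms / 125 ms windowing).
#'
#' @param segments A labelled `semg_segments`.
#' @param n_max Maximum number of windows to keep.
#' @param min_per_class Floor on windows kept per class (capped at the
#'   class count), so minority classes keep enough exemplars for
#'   cross-validation; the remaining budget is allocated proportionally.
#' @return The thinned `semg_segments`.
#' @export
thin_segments <- function(segments, n_max, min_per_class = 10L) {
  stopifnot(inherits(segments, "semg_segments"), !is.null(segments$labels))
  n <- length(segments$labels)
  if (n <= n_max) {
    return(segments)
  }
  classes <- sort(unique(segments$labels))
  counts <- vapply(classes, function(cl) sum(segments$labels == cl), integer(1))
  floor_take <- pmin(counts, min_per_class)
  if (sum(floor_take) >= n_max) {
    # budget smaller than the floors: share it near-equally across classes
    take <- allocate_proportional(n_max, floor_take)
  } else {
    take <- floor_take +
      allocate_proportional(n_max - sum(floor_take), pmax(counts - floor_take, 0))
    take <- pmin(take, counts)
  }
  keep <- integer(0)
  for (i in seq_along(classes)) {
    pos <- which(segments$labels == classes[i])
    if (take[i] >= 1) {
      sel <- unique(round(seq(1, length(pos), length.out = take[i])))
      keep <- c(keep, pos[sel])
    }
  }
  subset_segments(segments, sort(keep))
}

#' Mark event transition margins as invalid in a label track
#'
#' Returns the per-sample label track with the first and last `margin_s`
#' seconds of every non-rest event replaced by 0 ("no class"). Used when
#' selecting training windows so that windows overlapping the effort
#' onset/offset transients are excluded; windows labelled 0 (or mixed
#' with 0 under the `"pure"` policy) should then be dropped.
#'
#' @param labels Integer per-sample class labels.
#' @param fs Sampling rate, samples/s.
#' @param margin_s Margin trimmed from each end of every event, seconds.
#' @return Integer label track with 0 marking transition margins.
#' @export
core_label_track <- function(labels, fs, margin_s = 0.25) {
  if (margin_s <= 0) {
    return(labels)
  }
  m <- as.integer(round(margin_s * fs))
  out <- labels
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] == 1L) next
    a <- starts[i]
    b <- ends[i]
    out[a:min(b, a + m - 1L)] <- 0L
    out[max(a, b - m + 1L):b] <- 0L
  }
  out
}

#' @export
print.semg_segments <- function(x, ...) {
  cat(sprintf(
    "<semg_segments> %d windows of %d samples (step %d), subject %s%s\n",
    length(x$starts), x$window_samples, x$step_samples, x$subject_id,
    if (is.null(x$labels)) " (unlabelled)" else ""
  ))
  invisible(x)
}

n_segments <- function(segments) length(segments$starts)
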