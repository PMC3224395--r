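#' Write a recording as CSV plus JSON sidecar
#'
#' The data file is a plain CSV with columns exactly `time_s, ch_ED,
#' ch_PL, ch_FCU, ch_ECR, force_N, torque_Nm, label`; absent force/torque
#' tracks are written as empty fields. The JSON sidecar records the
#' sampling rate, subject metadata, protocol name, seed and strength
#' maxima, plus the sample count used to validate the CSV on read.
#' Numeric values are written with 17 significant digits so that a
#' read/write round trip reproduces samples exactly.
#'
#' @param recording A `semg_recording`.
#' @param data_path CSV output path.
#' @param meta_path JSON sidecar path; defaults to `data_path` with a
#'   `.json` extension.
#' @return Invisibly, a list with the two paths.
#' @export
write_recording <- function(recording, data_path, meta_path = NULL) {
  stopifnot(inherits(recording, "semg_recording"))
  meta_path <- meta_path %||% sidecar_path(data_path)
  n <- nrow(recording$channels)
  tracks <- list(recording$labels, recording$force, recording$torque)
  for (tr in tracks) {
    if (!is.null(tr) && length(tr) != n) stop("recording tracks have mismatched lengths")
  }
  fmt <- function(x) {
    if (is.null(x)) {
      return(rep("", n))
    }
    sprintf("%.17g", x)
  }
  df <- data.frame(
    time_s = fmt((seq_len(n) - 1) / recording$fs),
    ch_ED = fmt(recording$channels[, "ED"]),
    ch_PL = fmt(recording$channels[, "PL"]),
    ch_FCU = fmt(recording$channels[, "FCU"]),
    ch_ECR = fmt(recording$channels[, "ECR"]),
    force_N = fmt(recording$force),
    torque_Nm = fmt(recording$torque),
    label = recording$labels,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, data_path, row.names = FALSE, quote = FALSE)
  meta <- list(
    fs = recording$fs,
    subject_id = recording$subject$subject_id,
    group = recording$subject$group,
    protocol = recording$protocol,
    arm_position = recording$arm_position,
    seed = recording$seed,
    max_force = recording$subject$max_force,
    max_torque = recording$subject$max_torque,
    separability = recording$subject$separability,
    noise_floor = recording$subject$noise_floor,
    n_samples = n
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(list(data_path = data_path, meta_path = meta_path))
}

#' Read a recording written by [write_recording()]
#'
#' Readers validate rather than coerce: missing columns, labels outside
#' 1-15 and CSV/sidecar length mismatches are errors; a sampling rate
#' other than 1024 Hz is accepted with a warning.
#'
#' @param data_path CSV path.
#' @param meta_path JSON sidecar path; defaults to `data_path` with a
#'   `.json` extension.
#' @return A `semg_recording`.
#' @export
read_recording <- function(data_path, meta_path = NULL) {
  meta_path <- meta_path %||% sidecar_path(data_path)
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  if (!file.exists(meta_path)) stop("sidecar file not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(data_path, stringsAsFactors = FALSE,
    colClasses = c(force_N = "character", torque_Nm = "character")
  )
  required <- c("time_s", "ch_ED", "ch_PL", "ch_FCU", "ch_ECR", "force_N", "torque_Nm", "label")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("recording CSV is missing columns: ", paste(missing, collapse = ", "))
  if (!is.null(meta$n_samples) && nrow(df) != meta$n_samples) {
    stop(sprintf(
      "recording CSV has %d rows but the sidecar declares %d samples",
      nrow(df), meta$n_samples
    ))
  }
  bad <- which(!(df$label %in% CLASS_IDS))
  if (length(bad)) {
    stop(sprintf(
      "invalid class label %s at data row %d (labels must be 1-15)",
      df$label[bad[1]], bad[1]
    ))
  }
  if (!isTRUE(all.equal(meta$fs, 1024))) {
    warning("sampling rate is ", meta$fs, " Hz, not the standard 1024 Hz")
  }
  optional_track <- function(col) {
    if (all(col == "" | is.na(col))) {
      return(NULL)
    }
    as.numeric(col)
  }
  channels <- cbind(
    ED = as.numeric(df$ch_ED), PL = as.numeric(df$ch_PL),
    FCU = as.numeric(df$ch_FCU), ECR = as.numeric(df$ch_ECR)
  )
  profile <- subject_profile(
    subject_id = meta$subject_id,
    group = meta$group,
    max_force = meta$max_force,
    max_torque = meta$max_torque,
    separability = meta$separability %||% NULL,
    noise_floor = meta$noise_floor %||% 0.05
  )
  structure(
    list(
      fs = as.numeric(meta$fs),
      channels = channels,
      labels = as.integer(df$label),
      force = optional_track(df$force_N),
      torque = optional_track(df$torque_Nm),
      subject = profile,
      protocol = meta$protocol,
      arm_position = meta$arm_position %||% NA_character_,
      seed = as.integer(meta$seed)
    ),
    class = "semg_recording"
  )
}

sidecar_path <- function(data_path) {
  paste0(sub("\\.csv$", "", data_path), ".json")
}

#' Write / read a feature table CSV
#'
#' Feature tables are CSVs with columns `subject_id`, `window_index`,
#' `label` and the 24 feature columns named `<channel>_<feature>`
#' (`ED_wl`, `ED_rms`, `ED_ar1` ... `ECR_ar4`). Values are stored with 17
#' significant digits, so a round trip is exact. An empty table writes a
#' header-only file and reads back as an empty data.frame.
#'
#' @param features Feature table data.frame (see [extract_features()]).
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the feature table.
#' @export
write_feature_table <- function(features, path) {
  expected <- c("subject_id", "window_index", "label", feature_column_names())
  missing <- setdiff(expected, names(features))
  if (length(missing)) {
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  }
  out <- features[, expected, drop = FALSE]
  for (cn in feature_column_names()) out[[cn]] <- sprintf("%.17g", out[[cn]])
  if (nrow(out) == 0) {
    # header-only file
    writeLines(paste(expected, collapse = ","), path)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("subject_id", "window_index", "label", feature_column_names())
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop("feature table is missing columns: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), expected)
  if (length(extra)) {
    stop("feature table has unexpected columns: ", paste(extra, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df$window_index <- as.integer(df$window_index)
  df$label <- as.integer(df$label)
  for (cn in feature_column_names()) df[[cn]] <- as.numeric(df[[cn]])
  df
}
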