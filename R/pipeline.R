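#' Default pipeline configuration
#'
#' All tunable keys of the end-to-end pipeline with their defaults:
#' simulation (`fs`, protocol timing, generator noise terms),
#' segmentation (`window_ms` 250, `step_ms` 125, `label_policy` "pure",
#' `segments_per_protocol` 47 — about 6 s of signal per protocol),
#' features (`ar_order` 4, `ar_method` "burg"), classification
#' (`test_fraction` 0.1, `cv_folds` 8, the `(c, gamma)` grids,
#' `standardize`), the cohort layout (12 seniors, 7 young) and the master
#' `seed` from which all per-subject and per-recording seeds derive.
#'
#' @param ... Named overrides of any default key.
#' @return Named list of configuration values.
#' @examples
#' cfg <- default_config(seed = 7, n_senior = 2, n_young = 2)
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 42L,
    fs = 1024,
    protocols = c("C", "D", "E", "FC", "FD", "FE"),
    event_duration_s = 5,
    pinch_duration_s = 2.5,
    gap_s = 1,
    lead_in_s = 1,
    mvc_level = 0.5,
    comfortable_level = 0.4,
    gain = 1.0,
    event_gain_sd = 0.03,
    tremor_sd = 0.03,
    window_ms = 250,
    step_ms = 125,
    label_policy = "pure",
    event_margin_s = 0.25,
    segments_per_protocol = 47L,
    ar_order = 4L,
    ar_method = "burg",
    test_fraction = 0.1,
    cv_folds = 8L,
    c_grid = default_c_grid(),
    gamma_grid = default_gamma_grid(),
    standardize = TRUE,
    n_senior = 12L,
    n_young = 7L,
    out_dir = NULL,
    write_recordings = FALSE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML file of configuration overrides and merges it over
#' [default_config()]. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  overrides <- yaml::read_yaml(path)
  do.call(default_config, overrides %||% list())
}

config_protocols <- function(config) {
  stats::setNames(lapply(config$protocols, protocol_schedule,
    event_duration_s = config$event_duration_s,
    pinch_duration_s = config$pinch_duration_s,
    gap_s = config$gap_s, lead_in_s = config$lead_in_s,
    mvc_level = config$mvc_level,
    comfortable_level = config$comfortable_level
  ), config$protocols)
}

# Simulate -> segment -> label -> thin -> extract for one subject,
# returning the pooled feature table over all protocols.
subject_feature_table <- function(config, profile, subject_seed) {
  wp <- window_params(config$fs, config$window_ms, config$step_ms)
  schedules <- config_protocols(config)
  tables <- vector("list", length(schedules))
  for (j in seq_along(schedules)) {
    rec <- simulate_recording(
      schedules[[j]], profile,
      seed = derive_seed(subject_seed, j),
      fs = config$fs, gain = config$gain,
      event_gain_sd = config$event_gain_sd,
      tremor_sd = config$tremor_sd
    )
    seg <- segment_recording(rec, wp["window_samples"], wp["step_samples"])
    track <- core_label_track(rec$labels, config$fs, config$event_margin_s)
    seg <- assign_labels(seg, track, policy = config$label_policy)
    seg <- subset_segments(seg, which(seg$labels != 0L))
    seg <- thin_segments(seg, config$segments_per_protocol)
    tables[[j]] <- extract_features(seg,
      ar_order = config$ar_order, ar_method = config$ar_method
    )
    if (isTRUE(config$write_recordings) && !is.null(config$out_dir)) {
      write_recording(rec, file.path(
        config$out_dir,
        sprintf("%s_%s.csv", profile$subject_id, rec$protocol)
      ))
    }
  }
  out <- do.call(rbind, tables)
  # window_index is per-protocol; renumber to keep rows unique per subject
  out$window_index <- seq_len(nrow(out))
  out
}

#' Run the full classification pipeline for one subject
#'
#' Simulates the six-protocol battery for one subject, segments and
#' labels the recordings, extracts the 24-feature table, performs a
#' stratified 90/10 train/test split, tunes `(c, gamma)` by 8-fold
#' cross-validated grid search on the training partition, trains the
#' one-vs-one RBF-SVM at the selected point and scores the held-out test
#' windows. Fully reproducible under `config$seed`.
#'
#' @param config Configuration list from [default_config()].
#' @param profile Optional [subject_profile()]; defaults to the group
#'   defaults for `group`.
#' @param group Group used when `profile` is not given.
#' @param subject_index Index used to derive this subject's seed from the
#'   master seed.
#' @return A `semg_subject_run`: `report` (`semg_evaluation`),
#'   `grid_search`, `model`, `features`, `profile`, `config`.
#' @export
run_subject_pipeline <- function(config = default_config(), profile = NULL,
                                 group = "senior", subject_index = 1L) {
  if (is.null(profile)) {
    profile <- draw_cohort_profiles(1, group, seed = derive_seed(config$seed, 0L, subject_index))[[1]]
  }
  subject_seed <- derive_seed(config$seed, subject_index)
  features <- subject_feature_table(config, profile, subject_seed)
  parts <- split_train_test(features,
    test_fraction = config$test_fraction,
    seed = derive_seed(subject_seed, 100L)
  )
  gs <- grid_search_cv(parts$train,
    c_grid = config$c_grid, gamma_grid = config$gamma_grid,
    folds = config$cv_folds, seed = derive_seed(subject_seed, 200L),
    standardize = config$standardize
  )
  model <- train_svm(parts$train, gs$best, standardize = config$standardize)
  pred <- predict(model, parts$test)
  report <- score_predictions(pred, parts$test$label, subject_id = profile$subject_id)
  run <- structure(
    list(
      report = report,
      grid_search = gs,
      model = model,
      features = features,
      profile = profile,
      config = config
    ),
    class = "semg_subject_run"
  )
  if (!is.null(config$out_dir)) persist_subject_run(run, config$out_dir)
  run
}

persist_subject_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id <- run$profile$subject_id
  write_feature_table(run$features, file.path(out_dir, paste0(id, "_features.csv")))
  report <- run$report
  jsonlite::write_json(
    list(
      subject_id = id,
      accuracy_pct = report$accuracy,
      n_test = report$n,
      best_c = run$grid_search$best$c,
      best_gamma = run$grid_search$best$gamma,
      cv_accuracy_pct = max(run$grid_search$grid$cv_accuracy),
      confusion = report$confusion,
      per_class_recall = report$per_class_recall
    ),
    file.path(out_dir, paste0(id, "_report.json")),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  yaml::write_yaml(
    run$config[!vapply(run$config, is.null, logical(1))],
    file.path(out_dir, "config.yaml")
  )
  invisible(out_dir)
}

#' @export
print.semg_subject_run <- function(x, ...) {
  cat(sprintf(
    "<semg_subject_run> %s [%s]: best c = %g, gamma = %g; test accuracy %.2f%% (%d windows)\n",
    x$profile$subject_id, x$profile$group,
    x$grid_search$best$c, x$grid_search$best$gamma,
    x$report$accuracy, x$report$n
  ))
  invisible(x)
}

#' Run a two-group cohort study
#'
#' Draws `n_senior` senior and `n_young` young profiles, runs the
#' per-subject pipeline for each, and summarizes accuracy against
#' strength maxima with [cohort_summary()]. When `config$out_dir` is set,
#' a per-subject summary CSV (columns `subject`, `group`,
#' `accuracy_pct`, `max_force_N`, `max_torque_Nm`) and the resolved
#' configuration are written there.
#'
#' @param config Configuration list from [default_config()].
#' @param progress Print one line per subject as results arrive.
#' @return A `semg_cohort_study`: `summary` (`semg_cohort_summary`),
#'   `runs` (list of `semg_subject_run`), `config`.
#' @export
run_cohort_study <- function(config = default_config(), progress = FALSE) {
  groups <- c(
    rep("senior", config$n_senior %||% 0L),
    rep("young", config$n_young %||% 0L)
  )
  if (length(groups) == 0) stop("cohort config requests no subjects")
  profiles <- c(
    if (config$n_senior > 0) {
      draw_cohort_profiles(config$n_senior, "senior", seed = derive_seed(config$seed, 0L, 1L))
    },
    if (config$n_young > 0) {
      draw_cohort_profiles(config$n_young, "young", seed = derive_seed(config$seed, 0L, 2L))
    }
  )
  runs <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    runs[[i]] <- run_subject_pipeline(config,
      profile = profiles[[i]], subject_index = i
    )
    if (progress) print(runs[[i]])
  }
  subjects <- do.call(rbind, lapply(runs, function(r) {
    data.frame(
      subject = r$profile$subject_id,
      group = r$profile$group,
      accuracy_pct = r$report$accuracy,
      max_force_N = r$profile$max_force,
      max_torque_Nm = r$profile$max_torque,
      stringsAsFactors = FALSE
    )
  }))
  summary <- cohort_summary(subjects)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(subjects, file.path(config$out_dir, "cohort_subjects.csv"),
      row.names = FALSE
    )
    yaml::write_yaml(
      config[!vapply(config, is.null, logical(1))],
      file.path(config$out_dir, "config.yaml")
    )
  }
  structure(
    list(summary = summary, runs = runs, config = config),
    class = "semg_cohort_study"
  )
}

#' @export
print.semg_cohort_study <- function(x, ...) {
  cat(sprintf("<semg_cohort_study> %d subjects\n", nrow(x$summary$subjects)))
  print(x$summary)
  invisible(x)
}
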