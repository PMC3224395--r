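# Shared fixtures: small, fast objects built in code.

quick_profile <- function(group = "senior", id = "T01", ...) {
  subject_profile(id, group = group, ...)
}

# A short two-event schedule (grasp + ulnar deviation) for fast tests.
quick_schedule <- function() {
  s <- protocol_schedule("C", event_duration_s = 2, gap_s = 0.75, lead_in_s = 0.5)
  s$events <- data.frame(
    class_id = c(2L, 4L),
    start_s = c(0.5, 3.25),
    duration_s = c(2, 2),
    level = c(0.5, 0.5)
  )
  s$total_duration_s <- 6
  s
}

quick_recording <- function(seed = 1L, profile = quick_profile()) {
  simulate_recording(quick_schedule(), profile, seed = seed)
}

# Reduced-size pipeline configuration for fast end-to-end tests.
quick_config <- function(...) {
  default_config(
    protocols = c("C", "D", "E"),
    c_grid = c(1, 10, 100),
    gamma_grid = c(0.1, 0.5, 1.5),
    cv_folds = 4L,
    ...
  )
}

# Well-separated two-class Gaussian toy feature table.
toy_features <- function(n_per_class = 20, gap = 6, seed = 1, n_feat = 4) {
  set.seed(seed)
  x1 <- matrix(stats::rnorm(n_per_class * n_feat), n_per_class)
  x2 <- matrix(stats::rnorm(n_per_class * n_feat, mean = gap), n_per_class)
  x <- rbind(x1, x2)
  colnames(x) <- paste0("f", seq_len(n_feat))
  data.frame(
    subject_id = "toy",
    window_index = seq_len(2 * n_per_class),
    label = rep(1:2, each = n_per_class),
    x
  )
}
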