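#' Simulate an annotated multi-channel sEMG recording
#'
#' Generates a 4-channel surface EMG recording following a protocol
#' schedule. Each channel is an amplitude-modulated, band-limited
#' stochastic carrier: zero-mean Gaussian noise band-passed 20-450 Hz with
#' 4th-order Butterworth filters (surface EMG carries usable energy below
#' ~500 Hz; the 20 Hz high-pass suppresses the motion-artifact band).
#' The carrier mixes a low-frequency (20-120 Hz) and a high-frequency
#' (200-450 Hz) component with a weight that increases with contraction
#' intensity, emulating the upward shift of the sEMG power spectrum with
#' motor-unit recruitment — so the windowed AR coefficients, not just the
#' amplitude features, carry gesture information. The carrier is
#' multiplied by a per-muscle amplitude envelope
#'
#' \deqn{env_m(t) = noise\_floor + gain \times activation[m, class(t)]
#'   \times level(t)}
#'
#' where `level(t)` is a trapezoidal rise/hold/fall profile (0.25 s ramps)
#' for each scheduled event. Two human-variability terms perturb the
#' envelope: a per-event gain factor (a subject never hits the target
#' effort exactly) and a slow sinusoidal within-event fluctuation
#' (effort tremor). Force and torque sensor tracks follow the same
#' trapezoid scaled to `level * max_force` (grasp/pinch classes) or
#' `level * max_torque` (deviation classes, radial positive / ulnar
#' negative).
#'
#' Identical `(schedule, profile, seed)` give bit-identical output.
#'
#' @param schedule A [protocol_schedule()].
#' @param profile A [subject_profile()].
#' @param seed Integer seed.
#' @param fs Sampling rate, samples/s.
#' @param gain Envelope gain applied to activation levels, arbitrary sEMG
#'   units per unit activation.
#' @param ramp_s Trapezoid ramp duration, seconds.
#' @param event_gain_sd SD of the multiplicative per-event effort error.
#' @param tremor_sd Amplitude of the slow within-event effort fluctuation.
#' @param activation Optional precomputed activation matrix; defaults to
#'   [make_activation_matrix()] with subject-specific jitter derived from
#'   `seed` via the subject id (so a subject keeps one activation pattern
#'   across protocols simulated with seeds derived from one master seed).
#' @return A `semg_recording`: `fs`, `channels` (n x 4 matrix, columns ED,
#'   PL, FCU, ECR), `labels` (per-sample class id), `force`, `torque`,
#'   `subject`, `protocol`, `arm_position`, `seed`.
#' @export
simulate_recording <- function(schedule, profile, seed = 1L,
                               fs = 1024,
                               gain = 1.0,
                               ramp_s = 0.25,
                               event_gain_sd = 0.03,
                               tremor_sd = 0.03,
                               activation = NULL) {
  validate_schedule(schedule)
  stopifnot(inherits(profile, "semg_profile"), fs > 0)
  if (is.null(activation)) {
    act_seed <- derive_seed(sum(utf8ToInt(profile$subject_id)), 1L)
    activation <- make_activation_matrix(profile, seed = act_seed)
  }
  n <- as.integer(round(schedule$total_duration_s * fs))
  ev <- schedule$events
  tt <- (seq_len(n) - 1L) / fs

  labels <- rep(1L, n)
  level <- numeric(n) # trapezoid x jitter, shared by all muscles
  with_seed(derive_seed(seed, 1L), {
    for (i in seq_len(nrow(ev))) {
      i0 <- as.integer(floor(ev$start_s[i] * fs)) + 1L
      i1 <- min(n, as.integer(ceiling((ev$start_s[i] + ev$duration_s[i]) * fs)))
      idx <- i0:i1
      labels[idx] <- ev$class_id[i]
      tr <- trapezoid(tt[idx] - ev$start_s[i], ev$duration_s[i], ramp_s)
      g <- 1 + event_gain_sd * stats::rnorm(1)
      g <- max(0.5, g)
      f_hz <- stats::runif(1, 1, 3)
      phase <- stats::runif(1, 0, 2 * pi)
      flut <- 1 + tremor_sd * sin(2 * pi * f_hz * (tt[idx] - ev$start_s[i]) + phase)
      level[idx] <- ev$level[i] * g * tr * flut
    }
  })

  channels <- matrix(0, n, 4, dimnames = list(NULL, MUSCLES))
  for (m in seq_along(MUSCLES)) {
    low <- bandlimited_carrier(n, fs, derive_seed(seed, 2L, m), band = c(20, 120))
    high <- bandlimited_carrier(n, fs, derive_seed(seed, 4L, m), band = c(200, 450))
    drive <- gain * activation[m, labels] * level
    # Spectral content shifts upward with contraction intensity
    # (recruitment): mix low/high-band carriers by a drive-dependent
    # weight, so windowed AR coefficients reflect the active gesture.
    w <- pmin(0.9, 0.15 + 2.2 * drive)
    carrier <- sqrt(1 - w) * low + sqrt(w) * high
    env <- profile$noise_floor + drive
    channels[, m] <- env * carrier
  }

  # Sensor tracks: force for grasp/pinch events, torque for deviations.
  force <- numeric(n)
  torque <- numeric(n)
  is_force <- labels %in% FORCE_CLASSES
  is_radial <- labels %in% RADIAL_CLASSES
  is_ulnar <- labels %in% ULNAR_CLASSES
  force[is_force] <- level[is_force] * profile$max_force
  torque[is_radial] <- level[is_radial] * profile$max_torque
  torque[is_ulnar] <- -level[is_ulnar] * profile$max_torque
  with_seed(derive_seed(seed, 3L), {
    force <- force + stats::rnorm(n, sd = 0.005 * profile$max_force)
    torque <- torque + stats::rnorm(n, sd = 0.005 * profile$max_torque)
  })

  structure(
    list(
      fs = fs,
      channels = channels,
      labels = labels,
      force = force,
      torque = torque,
      subject = profile,
      protocol = schedule$name,
      arm_position = schedule$arm_position,
      seed = as.integer(seed)
    ),
    class = "semg_recording"
  )
}

# Trapezoidal rise/hold/fall profile on [0, duration], unit plateau.
trapezoid <- function(t_rel, duration, ramp_s) {
  ramp <- min(ramp_s, duration / 2)
  up <- pmin(1, pmax(0, t_rel / ramp))
  down <- pmin(1, pmax(0, (duration - t_rel) / ramp))
  pmin(up, down)
}

# Zero-mean Gaussian noise band-passed with a 4th-order Butterworth,
# normalized to unit RMS so the envelope sets the amplitude scale.
bandlimited_carrier <- function(n, fs, seed, band = c(20, 450)) {
  ny <- fs / 2
  bf <- signal::butter(4, c(band[1], min(band[2], 0.98 * ny)) / ny, type = "pass")
  pad <- as.integer(fs) # discard the filter transient
  x <- with_seed(seed, stats::rnorm(n + pad))
  y <- signal::filter(bf, x)
  y <- as.numeric(y)[(pad + 1L):(pad + n)]
  y / sqrt(mean(y^2))
}

#' Simulate a stationary autoregressive process
#'
#' Draws `n` samples from the AR(p) model
#' \deqn{t_n = \sum_{i=1}^{p} q_i t_{n-i} + w_n,\quad
#'   w_n \sim N(0, noise\_sd^2)}
#' (prediction-form sign convention: positive `q1` gives positive lag-1
#' autocorrelation). A burn-in period is generated and discarded so the
#' returned samples are from the stationary distribution.
#'
#' @param coefficients Numeric vector `q_1..q_p`.
#' @param n Number of samples to return.
#' @param noise_sd Innovation standard deviation.
#' @param seed Integer seed.
#' @param burn_in Samples discarded before the output (default
#'   `max(500, 10 * p)`).
#' @return Numeric vector of length `n`.
#' @examples
#' x <- simulate_ar_process(c(0.9), n = 1000, seed = 1)
#' @export
simulate_ar_process <- function(coefficients, n, noise_sd = 1, seed = 1L,
                                burn_in = NULL) {
  p <- length(coefficients)
  stopifnot(p >= 1, n >= 1, noise_sd > 0)
  # Stationarity: roots of 1 - q1 z - ... - qp z^p outside the unit circle.
  if (any(abs(coefficients) > 0)) {
    roots <- polyroot(c(1, -coefficients))
    if (any(Mod(roots) <= 1 + 1e-10)) {
      stop("AR coefficients are not stationary (characteristic root on or inside the unit circle)")
    }
  }
  burn_in <- burn_in %||% max(500L, 10L * p)
  w <- with_seed(seed, stats::rnorm(n + burn_in, sd = noise_sd))
  x <- as.numeric(stats::filter(w, coefficients, method = "recursive"))
  x[(burn_in + 1L):(burn_in + n)]
}

#' Simulate recordings for a whole cohort
#'
#' Draws `n_subjects` profiles from the group-level distributions (see
#' [draw_cohort_profiles()]) and simulates one recording per subject per
#' protocol, with per-recording seeds derived deterministically from
#' `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param group `"senior"` or `"young"`.
#' @param protocols List of schedules; defaults to [standard_protocols()].
#' @param seed Master integer seed.
#' @param ... Passed on to [simulate_recording()].
#' @return List of `semg_recording`, named `"<subject>_<protocol>"`.
#' @export
simulate_cohort <- function(n_subjects, group = c("senior", "young"),
                            protocols = standard_protocols(), seed = 1L, ...) {
  group <- match.arg(group)
  profiles <- draw_cohort_profiles(n_subjects, group, seed = derive_seed(seed, 0L))
  out <- list()
  for (i in seq_along(profiles)) {
    for (j in seq_along(protocols)) {
      rec <- simulate_recording(
        protocols[[j]], profiles[[i]],
        seed = derive_seed(seed, i, j), ...
      )
      out[[paste(profiles[[i]]$subject_id, rec$protocol, sep = "_")]] <- rec
    }
  }
  out
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf(
    "<semg_recording> %s protocol %s (%s): %d samples @ %g Hz, %d classes present\n",
    x$subject$subject_id, x$protocol, x$arm_position,
    nrow(x$channels), x$fs, length(unique(x$labels))
  ))
  invisible(x)
}
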