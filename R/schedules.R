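#' Timed gesture protocol schedules
#'
#' Builds the event timetable for one of the six data-collection protocols:
#'
#' * `C` / `FC` — three repetitions of a sustained grasp at 50% of the
#'   subject's maximum voluntary contraction (MVC), arm pronated /
#'   supinated.
#' * `D` / `FD` — three repetitions of alternating radial and ulnar wrist
#'   deviation at 50% MVC torque; each repetition block alternates
#'   radial/ulnar/radial/ulnar so the torque trace changes sign three
#'   times per block.
#' * `E` / `FE` — two pinches per finger (index, middle, ring, little)
#'   at a comfortable sub-maximal force.
#'
#' Gaps between events are rest (class 1). Durations are parameters: the
#' default sustained-effort repetition lasts 5 s, pinches 2.5 s, with 1 s
#' rest gaps.
#'
#' @param name One of `"C"`, `"D"`, `"E"`, `"FC"`, `"FD"`, `"FE"`.
#' @param event_duration_s Duration of one sustained repetition (protocols
#'   C/D and their supinated variants), seconds.
#' @param pinch_duration_s Duration of one pinch event, seconds.
#' @param gap_s Rest gap between events, seconds.
#' @param lead_in_s Initial rest period, seconds.
#' @param mvc_level Envelope level for C/D-type events, as a fraction of MVC.
#' @param comfortable_level Envelope level for pinch events.
#' @return A `semg_schedule`: name, arm position, event table
#'   (`class_id`, `start_s`, `duration_s`, `level`) and total duration.
#' @examples
#' protocol_schedule("D")
#' @export
protocol_schedule <- function(name = c("C", "D", "E", "FC", "FD", "FE"),
                              event_duration_s = 5,
                              pinch_duration_s = 2.5,
                              gap_s = 1,
                              lead_in_s = 1,
                              mvc_level = 0.5,
                              comfortable_level = 0.4) {
  name <- match.arg(name)
  stopifnot(
    event_duration_s > 0, pinch_duration_s > 0,
    gap_s >= 0, lead_in_s >= 0,
    mvc_level > 0, mvc_level <= 1,
    comfortable_level > 0, comfortable_level <= 1
  )
  supinated <- substr(name, 1, 1) == "F"
  kind <- if (supinated) substr(name, 2, 2) else name
  offset <- if (supinated) 7L else 0L
  ev <- switch(kind,
    C = {
      # three sustained grasps
      data.frame(
        class_id = rep(2L + offset, 3),
        duration_s = rep(event_duration_s, 3),
        level = rep(mvc_level, 3)
      )
    },
    D = {
      # three blocks, each radial/ulnar/radial/ulnar
      sub <- event_duration_s / 4
      data.frame(
        class_id = rep(c(3L, 4L, 3L, 4L) + offset, 3),
        duration_s = rep(sub, 12),
        level = rep(mvc_level, 12)
      )
    },
    E = {
      # two pinches per finger, index -> little
      data.frame(
        class_id = rep(5:8 + offset, each = 2),
        duration_s = rep(pinch_duration_s, 8),
        level = rep(comfortable_level, 8)
      )
    }
  )
  # Lay events out in time: within a D block the four sub-events are
  # contiguous (the torque alternates without returning to rest); gaps
  # separate repetitions/pinches.
  n <- nrow(ev)
  starts <- numeric(n)
  t <- lead_in_s
  for (i in seq_len(n)) {
    starts[i] <- t
    t <- t + ev$duration_s[i]
    contiguous <- kind == "D" && i %% 4 != 0
    if (!contiguous) t <- t + gap_s
  }
  ev$start_s <- starts
  ev <- ev[, c("class_id", "start_s", "duration_s", "level")]
  structure(
    list(
      name = name,
      arm_position = if (supinated) "supination" else "pronation",
      events = ev,
      total_duration_s = t
    ),
    class = "semg_schedule"
  )
}

#' Standard six-protocol battery
#'
#' The six class-bearing protocols (C, D, E in pronation; FC, FD, FE in
#' supination) with shared timing parameters.
#'
#' @inheritParams protocol_schedule
#' @return Named list of six `semg_schedule` objects.
#' @export
standard_protocols <- function(event_duration_s = 5, pinch_duration_s = 2.5,
                               gap_s = 1, lead_in_s = 1,
                               mvc_level = 0.5, comfortable_level = 0.4) {
  names <- c("C", "D", "E", "FC", "FD", "FE")
  stats::setNames(lapply(names, protocol_schedule,
    event_duration_s = event_duration_s,
    pinch_duration_s = pinch_duration_s,
    gap_s = gap_s, lead_in_s = lead_in_s,
    mvc_level = mvc_level, comfortable_level = comfortable_level
  ), names)
}

#' @export
print.semg_schedule <- function(x, ...) {
  cat(sprintf(
    "<semg_schedule> %s (%s), %d events, %.1f s total\n",
    x$name, x$arm_position, nrow(x$events), x$total_duration_s
  ))
  invisible(x)
}

validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "semg_schedule"))
  ev <- schedule$events
  if (nrow(ev) == 0) stop("schedule has no events")
  ends <- ev$start_s + ev$duration_s
  if (any(ends > schedule$total_duration_s + 1e-9)) {
    stop("schedule events exceed the recording duration")
  }
  ord <- order(ev$start_s)
  if (any(diff(ord) < 0)) stop("schedule events must be chronologically ordered")
  if (any(ends[-nrow(ev)] > ev$start_s[-1] + 1e-9)) {
    stop("schedule events overlap")
  }
  invisible(schedule)
}
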