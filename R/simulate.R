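#' Synthetic three-unit quaternion recordings
#'
#' The simulator emulates the wearable device's output for a catalogue of
#' twelve protocol tasks (seven static postures, five dynamic activities):
#' each unit streams 10 Hz unit quaternions composed of a posture
#' orientation, a shared trunk-motion component (slow postural sway plus
#' gait oscillations for dynamic tasks), compartment-specific breathing
#' micro-rotations at a controlled rate, per-sample sensor noise, and
#' counter-gap dropouts. Ground truth is emitted as a sidecar table, never
#' embedded in the quaternion log.
#'
#' @name simulator
NULL

PROTOCOL_TASKS <- c("sitting_support", "sitting_no_support", "supine",
                    "prone", "lying_left", "lying_right", "standing",
                    "walking_4kmh", "walking_6kmh", "running", "stairs",
                    "cycling")

HORIZONTAL_TASKS <- c("supine", "prone", "lying_left", "lying_right")

deg2rad <- function(x) x * pi / 180

task_defaults <- function(activity) {
  # posture = c(pitch, roll) degrees of the trunk's base orientation;
  # cadence in Hz, motion amplitude in degrees (roll at cadence, pitch at
  # twice the cadence and half amplitude); typical RR per task in bpm
  switch(activity,
    sitting_support    = list(posture = c(12, 0),   cadence = 0,   motion = 0,  rr = 14, noise_mult = 1),
    sitting_no_support = list(posture = c(5, 0),    cadence = 0,   motion = 0,  rr = 14, noise_mult = 1),
    supine             = list(posture = c(-85, 0),  cadence = 0,   motion = 0,  rr = 12, noise_mult = 1),
    prone              = list(posture = c(80, 0),   cadence = 0,   motion = 0,  rr = 12, noise_mult = 1),
    lying_left         = list(posture = c(0, -85),  cadence = 0,   motion = 0,  rr = 13, noise_mult = 1),
    lying_right        = list(posture = c(0, 85),   cadence = 0,   motion = 0,  rr = 13, noise_mult = 1),
    standing           = list(posture = c(0, 0),    cadence = 0,   motion = 0,  rr = 16, noise_mult = 1),
    walking_4kmh       = list(posture = c(3, 0),    cadence = 1.6, motion = 8,  rr = 20, noise_mult = 1),
    walking_6kmh       = list(posture = c(6, 0),    cadence = 1.9, motion = 9,  rr = 24, noise_mult = 1),
    running            = list(posture = c(10, 0),   cadence = 2.8, motion = 12, rr = 40, noise_mult = 1),
    stairs             = list(posture = c(15, 0),   cadence = 1.4, motion = 7,  rr = 26, noise_mult = 3),
    cycling            = list(posture = c(35, 0),   cadence = 1.5, motion = 5,  rr = 24, noise_mult = 1),
    stop("unknown protocol task '", activity, "'"))
}

#' Define a simulation scenario
#'
#' Free parameters the study protocol does not pin down (chest-wall rotation
#' amplitudes, gait cadences, noise level) default to realistic values:
#' breathing amplitude 2 degrees on the dominant compartment and 0.8 on the
#' other (thorax-dominant upright, abdomen-dominant horizontal), sensor
#' noise 0.15 degrees, 2% dropouts. Stair climbing triples the noise to
#' reproduce its characteristically poor signal-to-noise ratio.
#'
#' @param activity one of the twelve protocol tasks (see
#'   `quatresp:::PROTOCOL_TASKS`).
#' @param duration recording length in seconds (default 300, i.e. 5 min).
#' @param rr_bpm true respiratory rate in breaths/min, in `[5, 60]`;
#'   defaults to a typical value for the task.
#' @param breath_amp_deg length-2 vector `c(thorax, abdomen)` of breathing
#'   rotation amplitudes in degrees; default assigns dominance by posture.
#' @param cadence_hz gait cadence in Hz (0 for static tasks).
#' @param motion_amp_deg gait oscillation amplitude in degrees.
#' @param noise_deg per-sample angular noise standard deviation in degrees.
#' @param dropout_rate fraction of samples lost in transmission, `[0, 0.2)`.
#' @param seed integer seed driving all randomness of the scenario.
#' @return A `scenario` object (named list).
#' @export
scenario <- function(activity, duration = 300, rr_bpm = NULL,
                     breath_amp_deg = NULL, cadence_hz = NULL,
                     motion_amp_deg = NULL, noise_deg = 0.15,
                     dropout_rate = 0.02, seed = 1) {
  d <- task_defaults(activity)
  if (is.null(rr_bpm)) rr_bpm <- d$rr
  if (is.null(cadence_hz)) cadence_hz <- d$cadence
  if (is.null(motion_amp_deg)) motion_amp_deg <- d$motion
  if (is.null(breath_amp_deg))
    breath_amp_deg <- if (activity %in% HORIZONTAL_TASKS) c(0.8, 2) else c(2, 0.8)
  if (duration <= 0) stop("validation error: duration must be positive")
  if (rr_bpm < 5 || rr_bpm > 60)
    stop("validation error: rr_bpm must lie in [5, 60]")
  if (dropout_rate < 0 || dropout_rate >= 0.2)
    stop("validation error: dropout_rate must lie in [0, 0.2)")
  if (noise_deg < 0) stop("validation error: noise_deg must be >= 0")
  structure(list(activity = activity, duration = duration, rr_bpm = rr_bpm,
                 breath_amp_deg = breath_amp_deg, cadence_hz = cadence_hz,
                 motion_amp_deg = motion_amp_deg,
                 noise_deg = noise_deg * d$noise_mult,
                 posture_deg = d$posture, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' Default scenario catalogue: the twelve protocol tasks
#'
#' @param duration per-task duration in seconds.
#' @param seed base seed.
#' @return A named list of `scenario` objects, one per protocol task.
#' @export
scenario_catalogue <- function(duration = 300, seed = 1) {
  stats::setNames(lapply(seq_along(PROTOCOL_TASKS), function(i)
    scenario(PROTOCOL_TASKS[i], duration = duration, seed = seed + i)),
    PROTOCOL_TASKS)
}

rand_rotations <- function(n, sd_rad) {
  if (sd_rad <= 0) return(matrix(rep(c(1, 0, 0, 0), each = n), n, 4))
  axis <- matrix(stats::rnorm(3 * n), n, 3)
  axis <- axis / sqrt(rowSums(axis^2))
  half <- stats::rnorm(n, 0, sd_rad) / 2
  cbind(cos(half), sin(half) * axis)
}

axis_angle_series <- function(angle_rad, axis) {
  half <- angle_rad / 2
  axis <- axis / sqrt(sum(axis^2))
  cbind(cos(half), sin(half) * axis[1], sin(half) * axis[2], sin(half) * axis[3])
}

#' Simulate one three-unit recording
#'
#' The reference series is the posture orientation composed with the shared
#' trunk motion; thorax and abdomen carry an additional breathing
#' micro-rotation (sinusoidal angle about a fixed per-compartment axis) plus
#' a small unit-specific gait leak, so referencing cancels the shared motion
#' but not the breathing. Noise rotations are applied per unit per sample;
#' dropouts remove transmitted samples, which reappear as counter gaps in
#' the emitted log. The returned recording is re-assembled through the
#' ingest path ([as_recording()]), exactly as a logged file would be.
#'
#' @param s a [scenario()].
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier written into the log.
#' @return A list with `recording` (gap-filled, aligned), `log` (the
#'   `quat_log` with dropouts), and `truth` (data frame
#'   `t, rr_true_bpm, activity`).
#' @export
simulate_recording <- function(s, fs = 10, subject_id = "sim") {
  stopifnot(inherits(s, "scenario"))
  set.seed(s$seed)
  n <- round(s$duration * fs)
  t <- (0:(n - 1)) / fs
  f_b <- s$rr_bpm / 60

  # base posture orientation
  q0 <- quat_multiply(quat_from_axis_angle(deg2rad(s$posture_deg[1]), c(0, 1, 0)),
                      quat_from_axis_angle(deg2rad(s$posture_deg[2]), c(1, 0, 0)))

  # shared trunk motion: slow postural sway + gait oscillation
  sway <- quat_multiply(
    axis_angle_series(deg2rad(0.8) * sin(2 * pi * 0.03 * t + stats::runif(1, 0, 2 * pi)), c(1, 0, 0)),
    axis_angle_series(deg2rad(0.6) * sin(2 * pi * 0.02 * t + stats::runif(1, 0, 2 * pi)), c(0, 1, 0)))
  motion <- sway
  if (s$cadence_hz > 0) {
    gait <- quat_multiply(
      axis_angle_series(deg2rad(s$motion_amp_deg) * sin(2 * pi * s$cadence_hz * t), c(1, 0, 0)),
      axis_angle_series(deg2rad(s$motion_amp_deg / 2) * sin(4 * pi * s$cadence_hz * t + stats::runif(1, 0, 2 * pi)), c(0, 1, 0)))
    motion <- quat_multiply(motion, gait)
  }
  shared <- quat_multiply(matrix(q0, 1), motion)

  phase <- stats::runif(1, 0, 2 * pi)
  breath_th <- axis_angle_series(deg2rad(s$breath_amp_deg[1]) * sin(2 * pi * f_b * t + phase), c(0, 1, 0))
  breath_ab <- axis_angle_series(deg2rad(s$breath_amp_deg[2]) * sin(2 * pi * f_b * t + phase + 0.3), c(0, 1, 0))

  unit_q <- list()
  for (u in c("thorax", "abdomen", "reference")) {
    q <- shared
    if (u == "thorax") q <- quat_multiply(breath_th, q)
    if (u == "abdomen") q <- quat_multiply(breath_ab, q)
    if (s$cadence_hz > 0 && u != "reference") {
      # imperfect motion cancellation: small unit-specific gait component
      leak <- axis_angle_series(deg2rad(0.03 * s$motion_amp_deg) *
                                  sin(2 * pi * s$cadence_hz * t + stats::runif(1, 0, 2 * pi)),
                                c(0, 0, 1))
      q <- quat_multiply(leak, q)
    }
    q <- quat_multiply(rand_rotations(n, deg2rad(s$noise_deg)), q)
    unit_q[[u]] <- as_quat_matrix(quat_normalize(q))
  }

  records <- lapply(stats::setNames(names(unit_q), names(unit_q)), function(u) {
    keep <- rep(TRUE, n)
    if (s$dropout_rate > 0) {
      drop <- stats::runif(n) < s$dropout_rate
      drop[c(1, n)] <- FALSE
      keep <- !drop
    }
    data.frame(counter = (which(keep) - 1L) %% COUNTER_WRAP,
               t = t[keep],
               qw = unit_q[[u]][keep, 1], qx = unit_q[[u]][keep, 2],
               qy = unit_q[[u]][keep, 3], qz = unit_q[[u]][keep, 4])
  })
  log <- structure(list(subject_id = subject_id, records = records,
                        counts = vapply(records, nrow, integer(1)),
                        missing = vapply(records, function(r)
                          sum((diff(r$counter) - 1L) %% COUNTER_WRAP),
                          numeric(1))),
                   class = "quat_log")
  rec <- as_recording(log, fs = fs, label = s$activity)
  truth <- data.frame(t = t, rr_true_bpm = rep(s$rr_bpm, n),
                      activity = s$activity)
  list(recording = rec, log = log, truth = truth)
}

#' Write a simulated recording and its ground-truth sidecar
#'
#' @param sim output of [simulate_recording()].
#' @param path output CSV path for the quaternion log; the sidecar goes to
#'   `<path minus .csv>.truth.csv` with columns `t,rr_true_bpm,activity`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  write_quat_log(sim$log, path)
  truth_path <- paste0(sub("\\.csv$", "", path), ".truth.csv")
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  invisible(path)
}

#' Simulate a labeled corpus for activity recognition
#'
#' One recording per protocol task per synthetic subject, with seeded
#' subject-specific parameter jitter (respiratory rate +/-10%, breathing
#' amplitudes +/-20%, cadence +/-5%, posture orientation +/-4 degrees).
#' After label merging the corpus exposes exactly ten activity classes.
#'
#' @param catalogue list of `scenario` objects (default: the twelve-task
#'   [scenario_catalogue()]).
#' @param subjects number of synthetic subjects.
#' @param seed integer seed; the corpus is bit-identical for equal seeds.
#' @param duration per-task duration in seconds.
#' @return A list of `recording` objects with task labels and subject ids.
#' @export
simulate_har_corpus <- function(catalogue = NULL, subjects = 5, seed = 7,
                                duration = 300) {
  if (is.null(catalogue)) catalogue <- scenario_catalogue(duration = duration)
  if (!length(catalogue)) stop("validation error: empty scenario catalogue")
  stopifnot(subjects >= 1)
  set.seed(seed)
  corpus <- list()
  for (subj in seq_len(subjects)) {
    sid <- sprintf("S%02d", subj)
    for (k in seq_along(catalogue)) {
      base <- catalogue[[k]]
      jit <- scenario(
        activity = base$activity, duration = base$duration,
        rr_bpm = min(60, max(5, base$rr_bpm * stats::runif(1, 0.9, 1.1))),
        breath_amp_deg = base$breath_amp_deg * stats::runif(2, 0.8, 1.2),
        cadence_hz = if (base$cadence_hz > 0)
          base$cadence_hz * stats::runif(1, 0.95, 1.05) else 0,
        motion_amp_deg = base$motion_amp_deg,
        noise_deg = 0.15, dropout_rate = base$dropout_rate,
        seed = (seed * 1000L + subj * 50L + k) %% 2147483647L)
      jit$posture_deg <- base$posture_deg + stats::runif(2, -4, 4)
      sim <- simulate_recording(jit, subject_id = sid)
      corpus[[length(corpus) + 1L]] <- sim$recording
    }
  }
  corpus
}
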