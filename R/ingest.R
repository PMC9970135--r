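#' Quaternion log files and recordings
#'
#' The on-disk dialect is a plain CSV with header
#' `subject_id,unit_id,counter,t,qw,qx,qy,qz`: UTF-8, '.' decimal separator,
#' one row per transmitted sample. `counter` is the transmission counter kept
#' by the device firmware (one increment per transmitted quaternion, wrapping
#' at 256 because it travels in a single payload byte); gaps in the counter
#' mark lost transmissions. The simulator emits the same dialect plus a
#' ground-truth sidecar `t,rr_true_bpm,activity`.
#'
#' @name quaternion-log
NULL

LOG_HEADER <- c("subject_id", "unit_id", "counter", "t", "qw", "qx", "qy", "qz")
COUNTER_WRAP <- 256L
VALID_UNITS <- c("thorax", "abdomen", "reference")

fmt_num <- function(x) sprintf("%.12g", x)

#' Parse a quaternion log file
#'
#' Groups records by unit, orders them by time, and reports per-unit counts
#' and counter-gap statistics. No interpolation happens here; see
#' [as_recording()] for gap filling and alignment.
#'
#' @param path path to a CSV file in the documented log dialect.
#' @return A `quat_log` object: list with `subject_id`, `records` (named list
#'   of per-unit data frames with columns `counter, t, qw, qx, qy, qz`),
#'   `counts`, and `missing` (counter-gap sample counts per unit).
#' @export
parse_quat_log <- function(path) {
  if (!file.exists(path)) stop("log file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(
    subject_id = "character", unit_id = "character", counter = "integer",
    t = "numeric", qw = "numeric", qx = "numeric", qy = "numeric",
    qz = "numeric"))
  if (!identical(names(df), LOG_HEADER))
    stop("format error: header must be ", paste(LOG_HEADER, collapse = ","))
  bad <- setdiff(unique(df$unit_id), VALID_UNITS)
  if (length(bad))
    stop("format error: unknown unit_id ", paste(bad, collapse = ", "))
  subject <- unique(df$subject_id)
  if (length(subject) != 1L)
    stop("format error: expected a single subject per log, found ",
         length(subject))
  records <- lapply(split(df[setdiff(LOG_HEADER, c("subject_id", "unit_id"))],
                          df$unit_id), function(u) {
    if (any(diff(u$t) <= 0))
      stop("format error: non-monotone timestamps within a unit")
    rownames(u) <- NULL
    u
  })
  records <- records[intersect(VALID_UNITS, names(records))]
  missing <- vapply(records, function(u)
    sum((diff(u$counter) - 1L) %% COUNTER_WRAP), numeric(1))
  structure(list(subject_id = subject,
                 records = records,
                 counts = vapply(records, nrow, integer(1)),
                 missing = missing),
            class = "quat_log")
}

#' @export
print.quat_log <- function(x, ...) {
  cat(sprintf("<quat_log> subject=%s\n", x$subject_id))
  for (u in names(x$records))
    cat(sprintf("  %-9s %5d records, %d missing samples\n",
                u, x$counts[[u]], x$missing[[u]]))
  invisible(x)
}

#' Write a quaternion log file
#'
#' Inverse of [parse_quat_log()]: a parsed log written back reproduces the
#' records of a well-formed input file bit-exactly (the numeric formatter is
#' shared with the simulator's writer).
#'
#' @param log a `quat_log` object, or a `recording` (written with a fresh
#'   0-based counter per unit).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_quat_log <- function(log, path) {
  if (inherits(log, "recording")) log <- recording_to_log(log)
  stopifnot(inherits(log, "quat_log"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(LOG_HEADER, collapse = ","), con)
  for (u in intersect(VALID_UNITS, names(log$records))) {
    r <- log$records[[u]]
    writeLines(paste(log$subject_id, u, r$counter,
                     fmt_num(r$t), fmt_num(r$qw), fmt_num(r$qx),
                     fmt_num(r$qy), fmt_num(r$qz), sep = ","), con)
  }
  invisible(path)
}

recording_to_log <- function(rec) {
  records <- lapply(stats::setNames(VALID_UNITS, VALID_UNITS), function(u) {
    s <- rec[[u]]
    data.frame(counter = (seq_len(length(s)) - 1L) %% COUNTER_WRAP,
               t = s$t, qw = s$q[, 1], qx = s$q[, 2], qy = s$q[, 3],
               qz = s$q[, 4])
  })
  structure(list(subject_id = rec$subject_id, records = records,
                 counts = vapply(records, nrow, integer(1)),
                 missing = stats::setNames(numeric(3), VALID_UNITS)),
            class = "quat_log")
}

log_to_series <- function(log, unit, fs) {
  r <- log$records[[unit]]
  if (is.null(r)) stop("log has no records for unit ", unit)
  step <- c(0L, (diff(r$counter) - 1L) %% COUNTER_WRAP + 1L)
  idx <- cumsum(step)                       # 0-based position on the fs grid
  n <- idx[length(idx)] + 1L
  q <- matrix(NA_real_, n, 4)
  q[idx + 1L, ] <- cbind(r$qw, r$qx, r$qy, r$qz)
  t <- r$t[1] + (0:(n - 1L)) / fs
  quat_series(t, q, unit, fs = fs)
}

#' Fill counter-gap dropouts by interpolation
#'
#' Gap positions (all-`NA` rows inserted from the transmission counter) of
#' length `<= max_gap` samples are filled by component-wise linear
#' interpolation between the surrounding samples, then renormalized to unit
#' norm. At 10 Hz and the sub-second gaps the radio link produces, linear
#' interpolation of the components stays within 1e-3 of spherical
#' interpolation for rotations up to a few degrees.
#'
#' @param series a `quat_series`, possibly containing `NA` gap rows.
#' @param max_gap longest fillable gap, in samples (default 10 = 1 s).
#' @return The filled `quat_series`; indices of filled samples are recorded
#'   in `attr(, "filled")`.
#' @export
fill_missing <- function(series, max_gap = 10) {
  stopifnot(inherits(series, "quat_series"), max_gap >= 1)
  miss <- is.na(series$q[, 1])
  if (!any(miss)) {
    attr(series, "filled") <- integer(0)
    return(series)
  }
  if (miss[1] || miss[length(miss)])
    stop("unfillable gap: series starts or ends with missing samples")
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  too_long <- runs$values & runs$lengths > max_gap
  if (any(too_long)) {
    i <- which(too_long)[1]
    stop(sprintf("unfillable gap: %d missing samples in [%.2f, %.2f] s exceeds max_gap = %d",
                 runs$lengths[i], series$t[starts[i]], series$t[ends[i]], max_gap))
  }
  obs <- which(!miss)
  q <- series$q
  for (k in 1:4)
    q[miss, k] <- stats::approx(obs, q[obs, k], xout = which(miss))$y
  out <- quat_series(series$t, q, series$unit_id, fs = series$fs)
  attr(out, "filled") <- which(miss)
  out
}

#' Assemble an aligned three-unit recording from a parsed log
#'
#' Reconstructs each unit's 10 Hz sample grid from the transmission counter,
#' fills dropouts with [fill_missing()], and aligns the three units on their
#' common time span.
#'
#' @param log a `quat_log` from [parse_quat_log()].
#' @param fs sampling rate in Hz.
#' @param max_gap passed to [fill_missing()].
#' @param label activity label (defaults to `NA`).
#' @return A `recording` object.
#' @export
as_recording <- function(log, fs = 10, max_gap = 10, label = NA_character_) {
  stopifnot(inherits(log, "quat_log"))
  series <- lapply(stats::setNames(VALID_UNITS, VALID_UNITS), function(u)
    fill_missing(log_to_series(log, u, fs), max_gap = max_gap))
  t0 <- max(vapply(series, function(s) s$t[1], numeric(1)))
  t1 <- min(vapply(series, function(s) s$t[length(s)], numeric(1)))
  if (t1 <= t0) stop("alignment error: units share no common time span")
  series <- lapply(series, function(s) {
    keep <- s$t >= t0 - 1e-9 & s$t <= t1 + 1e-9
    quat_series(s$t[keep], s$q[keep, , drop = FALSE], s$unit_id, fs = fs)
  })
  n <- unique(vapply(series, length, integer(1)))
  if (length(n) != 1L)
    stop("alignment error: units disagree on the common grid")
  recording(series$thorax, series$abdomen, series$reference, fs = fs,
            label = label, subject_id = log$subject_id)
}

#' Read a recording directly from a log file
#'
#' Convenience wrapper: [parse_quat_log()] then [as_recording()].
#'
#' @inheritParams parse_quat_log
#' @inheritParams as_recording
#' @return A `recording`.
#' @export
read_recording <- function(path, fs = 10, max_gap = 10, label = NA_character_) {
  as_recording(parse_quat_log(path), fs = fs, max_gap = max_gap, label = label)
}

#' Construct an aligned three-unit recording
#'
#' @param thorax,abdomen,reference `quat_series` of equal length on the same
#'   timestamp grid.
#' @param fs sampling rate in Hz; must be positive.
#' @param label activity label, or `NA`.
#' @param subject_id free-text subject identifier.
#' @return A `recording` object (list with the three series plus metadata).
#' @export
recording <- function(thorax, abdomen, reference, fs = 10,
                      label = NA_character_, subject_id = "anon") {
  stopifnot(inherits(thorax, "quat_series"), inherits(abdomen, "quat_series"),
            inherits(reference, "quat_series"), fs > 0)
  n <- c(length(thorax), length(abdomen), length(reference))
  if (length(unique(n)) != 1L)
    stop("alignment error: series have different lengths")
  if (max(abs(thorax$t - reference$t), abs(abdomen$t - reference$t)) > 1e-9)
    stop("alignment error: timestamps do not match across units")
  structure(list(thorax = thorax, abdomen = abdomen, reference = reference,
                 fs = fs, label = label, subject_id = subject_id,
                 trim = NULL),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject=%s  label=%s  fs=%g Hz  n=%d (%.1f s)%s\n",
              x$subject_id, x$label, x$fs, length(x$thorax),
              length(x$thorax) / x$fs,
              if (is.null(x$trim)) "" else
                sprintf("  trimmed=[%g, %g) s", x$trim[1], x$trim[2])))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `recording`.
#' @return Duration in seconds (`n / fs`).
#' @export
recording_duration <- function(rec) length(rec$thorax) / rec$fs

#' Trim a recording to a time window
#'
#' Cuts all three series to `[start, end)` seconds relative to the start of
#' the recording. Used to discard the transient period at the beginning of
#' each activity, before the sensor-fusion quaternions stabilize.
#'
#' @param rec a `recording`.
#' @param start,end window bounds in seconds, `0 <= start < end <= duration`.
#' @return The trimmed `recording`; the window is recorded in `$trim`.
#' @export
trim_window <- function(rec, start, end) {
  stopifnot(inherits(rec, "recording"))
  dur <- recording_duration(rec)
  if (start < 0 || start >= end || end > dur + 1e-9)
    stop(sprintf("bounds error: need 0 <= start < end <= %.1f, got [%g, %g)",
                 dur, start, end))
  rel <- rec$thorax$t - rec$thorax$t[1]
  keep <- rel >= start - 1e-9 & rel < end - 1e-9
  out <- rec
  for (u in VALID_UNITS) {
    s <- rec[[u]]
    out[[u]] <- quat_series(s$t[keep], s$q[keep, , drop = FALSE], s$unit_id,
                            fs = rec$fs)
  }
  out$trim <- c(start, end)
  out
}
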