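#' Activity presets for the respiratory-peak search
#'
#' Each preset fixes the floor of the adaptive low-frequency threshold
#' (`f_thresh_min`) and the upper bound of the spectral peak search
#' (`f_search_max`). Static postures use a permissive 0.05 Hz floor and a
#' 1 Hz ceiling; dynamic activities raise the floor (0.2 Hz for walking and
#' cycling, 0.4 Hz for running) to reject low-frequency movement artifacts,
#' and adjust the ceiling (0.75 Hz walking/cycling, 1.4 Hz running) to the
#' physiologically plausible breathing range for that effort.
#'
#' @param name preset name: `"static"`, `"walking"`, `"cycling"`, or
#'   `"running"`.
#' @return `activity_preset()`: a list with `name`, `f_thresh_min` (Hz) and
#'   `f_search_max` (Hz). `activity_presets()`: the full preset table as a
#'   data frame.
#' @export
activity_preset <- function(name = c("static", "walking", "cycling", "running")) {
  name <- match.arg(name)
  p <- activity_presets()
  row <- p[p$name == name, ]
  structure(list(name = row$name, f_thresh_min = row$f_thresh_min,
                 f_search_max = row$f_search_max),
            class = "activity_preset")
}

#' @rdname activity_preset
#' @export
activity_presets <- function() {
  data.frame(name = c("static", "walking", "cycling", "running"),
             f_thresh_min = c(0.05, 0.2, 0.2, 0.4),
             f_search_max = c(1.0, 0.75, 0.75, 1.4),
             stringsAsFactors = FALSE)
}

#' @export
print.activity_preset <- function(x, ...) {
  cat(sprintf("<activity_preset> %s: f_thresh_min=%g Hz, f_search_max=%g Hz\n",
              x$name, x$f_thresh_min, x$f_search_max))
  invisible(x)
}

STATIC_LABELS <- c("sitting", "sitting_support", "sitting_no_support",
                   "supine", "prone", "lying_left", "lying_right", "standing")

#' Map an activity label to its processing preset
#'
#' Static postures map to the `static` preset; walking (any speed), cycling
#' and stair climbing to their gait presets; running to `running`. Stair
#' climbing uses the walking preset: its cadence and breathing range are
#' walking-like, though its signal-to-noise ratio is typically poor (the
#' pipeline flags this via the low-SNR quality flag rather than refusing).
#'
#' @param label an activity label (task names such as `"walking_4kmh"` are
#'   accepted).
#' @return An `activity_preset`.
#' @export
preset_for_label <- function(label) {
  merged <- merge_activity_label(label)
  name <- if (merged %in% STATIC_LABELS) "static"
  else switch(merged,
              walking = "walking", stairs = "walking",
              cycling = "cycling", running = "running",
              stop("no preset known for activity label '", label, "'"))
  activity_preset(name)
}
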