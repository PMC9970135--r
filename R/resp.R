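#' Respiratory-rate estimation pipeline
#'
#' The quaternion-to-RR chain: relative orientation against the reference
#' unit, 97-sample moving-average baseline removal per quaternion component,
#' PCA reduction to a single respiratory waveform, Savitzky-Golay smoothing
#' (order 3, 31 samples), inter-peak threshold estimation with an
#' activity-dependent floor, Welch spectral peak search (Hamming window, 300
#' samples, 50 overlap) bounded by the merged low threshold and the preset
#' ceiling, an adaptive band-pass of +/- 0.04 Hz around the spectral peak,
#' and tuned maxima/minima detection yielding breath-by-breath RR for the
#' thoracic signal, the abdominal signal, and their sum.
#'
#' @name resp-pipeline
NULL

#' Default configuration of the RR pipeline
#'
#' All numeric knobs of [estimate_rr()] with their defaults. Values carried
#' over from the validated static-posture algorithm: `baseline_window` 97
#' samples, `sg_order` 3 and `sg_window` 31 samples, Welch window 300 samples
#' with 50 overlap, band half-width 0.04 Hz. The breath-detection tuning map
#' (`sg2_factor`, `min_dist_factor`, `prominence_factor`) scales the second
#' smoothing window, the minimum peak distance and the prominence floor with
#' the located breathing frequency.
#'
#' @param ... overrides for individual keys.
#' @return A named list of configuration values.
#' @export
rr_config <- function(...) {
  cfg <- list(baseline_window = 97L, sg_order = 3L, sg_window = 31L,
              welch_window = 300L, welch_overlap = 50L, band_delta = 0.04,
              sg2_factor = 0.6, min_dist_factor = 0.5,
              prominence_factor = 0.2, snr_ratio = 3,
              threshold_prominence_factor = 0.1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

centered_mean <- function(x, window) {
  # symmetric moving average; the window shrinks symmetrically at the edges
  n <- length(x)
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  k <- pmin(h, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
}

#' Remove the slow baseline from quaternion components
#'
#' Per component, subtracts a centered moving average (default 97 samples,
#' i.e. 9.7 s at 10 Hz) that tracks residual non-breathing movement left
#' after referencing. The window shrinks symmetrically at the recording
#' edges, so no padding values are fabricated.
#'
#' @param q a `quat_series` (typically from [relative_series()]) or an
#'   n x 4 numeric matrix of components.
#' @param window moving-average length in samples; must be odd.
#' @return An n x 4 matrix of zero-baseline components.
#' @export
remove_baseline <- function(q, window = 97) {
  m <- if (inherits(q, "quat_series")) q$q else as_quat_matrix(q)
  if (window %% 2 == 0) stop("baseline window must be odd")
  if (nrow(m) <= window)
    stop("insufficient data: series length ", nrow(m),
         " not greater than baseline window ", window)
  out <- m
  for (k in 1:4) out[, k] <- m[, k] - centered_mean(m[, k], window)
  out
}

#' Extract the respiratory waveform by principal component analysis
#'
#' Projects the four zero-baseline quaternion components onto the leading
#' eigenvector of their covariance; the first principal component carries
#' the greatest share of variance and is taken as the respiratory signal.
#' The sign is fixed deterministically: the score is oriented so that its
#' correlation with the first input component is non-negative (ties resolved
#' toward a positive first loading).
#'
#' @param components n x 4 matrix of zero-baseline components.
#' @return A list with `samples` (the PC1 score vector) and
#'   `variance_explained` (fraction of total variance in `[0, 1]`).
#' @export
extract_pc1 <- function(components) {
  m <- as_quat_matrix(components)
  if (nrow(m) < 2) stop("need at least 2 samples for PCA")
  total_var <- sum(apply(m, 2, stats::var))
  if (total_var < .Machine$double.eps)
    stop("degenerate input: all components are constant")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  flip <- {
    s1 <- stats::sd(m[, 1])
    r <- if (s1 > 0 && stats::sd(score) > 0) stats::cor(score, m[, 1]) else 0
    if (abs(r) > 1e-12) r < 0 else pc$rotation[1, 1] < 0
  }
  if (flip) score <- -score
  list(samples = as.numeric(score),
       variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Savitzky-Golay smoothing
#'
#' Thin wrapper over [signal::sgolayfilt()] with the pipeline's defaults
#' (3rd-order polynomial, 31-sample window): reduces noise without changing
#' peak shape or height. The window is clamped to an odd value not exceeding
#' the signal length.
#'
#' @param x numeric signal.
#' @param order polynomial order.
#' @param window window length in samples (odd).
#' @return The smoothed signal, same length as `x`.
#' @export
sg_smooth <- function(x, order = 3, window = 31) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > length(x)) {
    window <- length(x) - (1L - length(x) %% 2L)
    if (window <= order) return(x)
  }
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Locate signal peaks with prominence and distance control
#'
#' Local maxima filtered by topographic prominence, then thinned tallest
#' first: the algorithm keeps the tallest remaining peak and discards every
#' peak closer than `min_distance` samples to an already kept one.
#'
#' @param x numeric signal.
#' @param min_distance minimum separation between kept peaks, in samples.
#' @param min_prominence minimum topographic prominence.
#' @return Sorted integer indices of the kept peaks.
#' @export
find_peaks <- function(x, min_distance = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || min(abs(kept - i)) >= min_distance)
      kept <- c(kept, i)
  sort(kept)
}

peak_prominence <- function(x, i) {
  # lowest descent needed to reach higher ground (or a signal edge) on the
  # shallower side
  n <- length(x)
  left <- x[i]
  j <- i - 1L
  lmin <- x[i]
  while (j >= 1L && x[j] <= x[i]) {
    lmin <- min(lmin, x[j])
    j <- j - 1L
  }
  j <- i + 1L
  rmin <- x[i]
  while (j <= n && x[j] <= x[i]) {
    rmin <- min(rmin, x[j])
    j <- j + 1L
  }
  x[i] - max(lmin, rmin)
}

#' Adaptive low-frequency threshold from inter-peak intervals
#'
#' The respiratory waveform is Savitzky-Golay smoothed (order 3, 31
#' samples); the inverses of the distances between subsequent peaks give
#' instantaneous frequency estimates whose mean `f_mean` and standard
#' deviation `f_std` set the threshold `f_thresh = max(f_thresh_min,
#' f_mean - f_std)`, with the floor `f_thresh_min` taken from the activity
#' preset. With fewer than 3 detected peaks the estimate falls back to the
#' floor and is flagged.
#'
#' @param x the respiratory waveform (PC1 samples).
#' @param preset an [activity_preset()].
#' @param fs sampling rate in Hz.
#' @param compartment label stored in the result.
#' @param config see [rr_config()].
#' @return A `threshold_estimate`: list with `f_mean`, `f_std`, `f_thresh`
#'   (Hz), `compartment`, and `fallback` flag.
#' @export
compute_threshold <- function(x, preset, fs = 10,
                              compartment = c("thorax", "abdomen"),
                              config = rr_config()) {
  compartment <- match.arg(compartment)
  if (length(x) < config$sg_window)
    stop("insufficient data: need at least ", config$sg_window, " samples")
  sm <- sg_smooth(x, config$sg_order, config$sg_window)
  d <- max(1L, floor(fs / preset$f_search_max))
  pk <- find_peaks(sm, min_distance = d,
                   min_prominence = config$threshold_prominence_factor * stats::sd(sm))
  if (length(pk) < 3)
    return(threshold_from_stats(NA_real_, NA_real_, preset, compartment,
                                fallback = TRUE))
  f_inst <- fs / diff(pk)
  threshold_from_stats(mean(f_inst), stats::sd(f_inst), preset, compartment)
}

#' Threshold from precomputed frequency statistics
#'
#' Closed-form core of [compute_threshold()]:
#' `f_thresh = max(f_thresh_min, f_mean - f_std)`.
#'
#' @param f_mean,f_std mean and standard deviation of the instantaneous
#'   breathing-frequency estimates, in Hz.
#' @inheritParams compute_threshold
#' @param fallback set when peak statistics were unavailable; the threshold
#'   is then the preset floor.
#' @return A `threshold_estimate`.
#' @export
threshold_from_stats <- function(f_mean, f_std, preset,
                                 compartment = "thorax", fallback = FALSE) {
  f_thresh <- if (fallback) preset$f_thresh_min
  else max(preset$f_thresh_min, f_mean - f_std)
  structure(list(f_mean = f_mean, f_std = f_std, f_thresh = f_thresh,
                 f_thresh_min = preset$f_thresh_min,
                 compartment = compartment, fallback = fallback),
            class = "threshold_estimate")
}

#' Merge the per-compartment low thresholds
#'
#' The band-search floor shared by both compartments is the minimum of the
#' thoracic and abdominal thresholds.
#'
#' @param thorax,abdomen `threshold_estimate` objects.
#' @return The merged low threshold in Hz.
#' @export
merge_thresholds <- function(thorax, abdomen) {
  stopifnot(inherits(thorax, "threshold_estimate"),
            inherits(abdomen, "threshold_estimate"))
  min(thorax$f_thresh, abdomen$f_thresh)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram over Hamming-tapered segments (default 300
#' samples, 50 samples overlap); each segment is mean-detrended before
#' tapering. One-sided density scaling.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param window segment length in samples.
#' @param overlap overlap between consecutive segments in samples.
#' @return A list with `freq` (Hz) and `psd` (power/Hz).
#' @export
welch_psd <- function(x, fs = 10, window = 300, overlap = 50) {
  n <- length(x)
  if (n < window)
    stop("insufficient data: signal length ", n,
         " is shorter than one Welch window (", window, ")")
  step <- window - overlap
  k <- (n - window) %/% step + 1L
  taper <- 0.54 - 0.46 * cos(2 * pi * (0:(window - 1)) / (window - 1))
  scale <- fs * sum(taper^2)
  nf <- window %/% 2L + 1L
  acc <- numeric(nf)
  for (s in seq_len(k)) {
    seg <- x[(s - 1L) * step + seq_len(window)]
    seg <- (seg - mean(seg)) * taper
    p <- abs(stats::fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    if (window %% 2L == 1L) p[nf] <- 2 * p[nf]
    acc <- acc + p
  }
  list(freq = (0:(nf - 1L)) * fs / window, psd = acc / k)
}

#' Locate the respiratory spectral peak
#'
#' Restricts the Welch PSD to `[f_low, f_max]` and returns the frequency of
#' its maximum; ties break toward the lower frequency. The ratio of the peak
#' to the median in-band density is reported as a signal-to-noise indicator.
#'
#' @param x the (smoothed) respiratory waveform.
#' @param f_low,f_max search band bounds in Hz, `f_low < f_max <= fs/2`.
#' @inheritParams welch_psd
#' @return A list with `f_peak` (Hz), `freq`, `psd`, and `snr` (peak /
#'   median in-band PSD).
#' @export
welch_find_peak <- function(x, f_low, f_max, fs = 10, window = 300,
                            overlap = 50) {
  if (f_low >= f_max) stop("band error: f_low >= f_max")
  if (f_max > fs / 2 + 1e-12) stop("band error: f_max above Nyquist")
  w <- welch_psd(x, fs = fs, window = window, overlap = overlap)
  in_band <- w$freq >= f_low & w$freq <= f_max
  if (!any(in_band)) stop("band error: no spectral bins in [", f_low, ", ",
                          f_max, "] Hz")
  fb <- w$freq[in_band]
  pb <- w$psd[in_band]
  i <- which.max(pb)   # first maximum = lowest frequency on ties
  list(f_peak = fb[i], freq = w$freq, psd = w$psd,
       snr = pb[i] / stats::median(pb))
}

#' Adaptive band-pass edges around the spectral peak
#'
#' `f_U = f_peak + 0.04` Hz and `f_L = max(f_thresh_m, f_peak - 0.04)` Hz,
#' where `f_thresh_m` is the merged low threshold from
#' [merge_thresholds()].
#'
#' @param f_peak located breathing frequency in Hz.
#' @param merged_low_threshold merged low threshold in Hz.
#' @param delta band half-width in Hz.
#' @return A `bandpass_spec`: list with `f_peak`, `f_L`, `f_U`,
#'   `merged_low_threshold`.
#' @export
design_bandpass <- function(f_peak, merged_low_threshold, delta = 0.04) {
  stopifnot(f_peak > 0)
  f_U <- f_peak + delta
  f_L <- max(merged_low_threshold, f_peak - delta)
  if (f_L >= f_U)
    stop(sprintf("degenerate band: f_L = %.3f >= f_U = %.3f Hz", f_L, f_U))
  structure(list(f_peak = f_peak, f_L = f_L, f_U = f_U,
                 merged_low_threshold = merged_low_threshold),
            class = "bandpass_spec")
}

#' @export
print.bandpass_spec <- function(x, ...) {
  cat(sprintf("<bandpass_spec> f_peak=%.3f Hz, band=[%.3f, %.3f] Hz\n",
              x$f_peak, x$f_L, x$f_U))
  invisible(x)
}

#' Apply the adaptive band-pass filter
#'
#' Order-2 Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]), giving zero phase distortion (effective order 4)
#' so breath peak timing is preserved. Edges are clamped to
#' `(1e-3, fs/2 - 1e-3)` Hz.
#'
#' @param x numeric signal.
#' @param band a `bandpass_spec`.
#' @param fs sampling rate in Hz.
#' @return The filtered signal.
#' @export
apply_bandpass <- function(x, band, fs = 10) {
  stopifnot(inherits(band, "bandpass_spec"))
  if (band$f_L >= fs / 2 || band$f_U <= 0)
    stop("band error: edges outside (0, fs/2)")
  lo <- max(band$f_L, 1e-3)
  hi <- min(band$f_U, fs / 2 - 1e-3)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect breaths in the band-passed waveform
#'
#' Parametric tuning driven by the located breathing frequency: the signal
#' is smoothed a second time with an order-3 Savitzky-Golay filter whose
#' window spans `sg2_factor` of the breathing period (odd, at least 5
#' samples); maxima and minima are then detected keeping the tallest peaks
#' and ignoring peaks within `min_dist_factor / f_peak` seconds or below a
#' prominence of `prominence_factor` times the band-passed signal's standard
#' deviation. RR is derived breath by breath as 60 over the interval between
#' consecutive maxima.
#'
#' @param x band-passed respiratory waveform.
#' @param f_peak located breathing frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds (for reported peak times).
#' @param config see [rr_config()].
#' @return A `breath_table`: list with `peak_times`, `trough_times`
#'   (seconds), `rr_bpm` (one value per interval between consecutive
#'   maxima), and `flags`.
#' @export
detect_breaths <- function(x, f_peak, fs = 10, t0 = 0, config = rr_config()) {
  stopifnot(f_peak > 0)
  w <- max(5L, round(config$sg2_factor * fs / f_peak))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- sg_smooth(x, config$sg_order, w)
  d <- max(1L, round(config$min_dist_factor * fs / f_peak))
  prom <- config$prominence_factor * stats::sd(x)
  maxima <- find_peaks(sm, min_distance = d, min_prominence = prom)
  minima <- find_peaks(-sm, min_distance = d, min_prominence = prom)
  flags <- character(0)
  if (!length(maxima)) flags <- "no_peaks"
  # sub-sample peak timing by quadratic interpolation around each maximum,
  # so breath intervals are not quantized to the 10 Hz grid
  peak_pos <- refine_peaks(sm, maxima)
  trough_pos <- refine_peaks(-sm, minima)
  rr <- if (length(maxima) >= 2) 60 * fs / diff(peak_pos) else numeric(0)
  structure(list(peak_times = t0 + (peak_pos - 1) / fs,
                 trough_times = t0 + (trough_pos - 1) / fs,
                 rr_bpm = rr, flags = flags),
            class = "breath_table")
}

#' @export
print.breath_table <- function(x, ...) {
  cat(sprintf("<breath_table> %d breaths, median RR = %s bpm%s\n",
              length(x$peak_times),
              if (length(x$rr_bpm)) sprintf("%.1f", stats::median(x$rr_bpm)) else "NA",
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

refine_peaks <- function(x, idx) {
  if (!length(idx)) return(numeric(0))
  pos <- as.numeric(idx)
  interior <- idx > 1L & idx < length(x)
  i <- idx[interior]
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  shift <- ifelse(abs(denom) < .Machine$double.eps, 0,
                  0.5 * (x[i - 1L] - x[i + 1L]) / denom)
  pos[interior] <- i + pmax(-0.5, pmin(0.5, shift))
  pos
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s stage] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Estimate respiratory rate from a three-unit recording
#'
#' Runs the full chain on the thoracic and abdominal signals and on their
#' sum: referencing, baseline removal, PCA, Savitzky-Golay smoothing,
#' per-compartment threshold estimation and merging, Welch peak search,
#' adaptive band-pass, and tuned breath detection. The sum signal is the sum
#' of the two band-pass-filtered compartment waveforms, detected with the
#' thoracic tuning.
#'
#' @param rec a `recording`.
#' @param preset an [activity_preset()], or a preset name, or `NULL` to
#'   derive it from the recording's activity label.
#' @param config see [rr_config()].
#' @return An `rr_result`: breath tables and median RR per compartment
#'   (`thorax`, `abdomen`, `sum`), the thresholds, spectral peaks, bands,
#'   PCA variance explained, preset name, and quality flags (`low_snr` when
#'   the spectral peak does not exceed `snr_ratio` times the median in-band
#'   density, as happens for stair climbing; `threshold_fallback`;
#'   `no_peaks`).
#' @export
estimate_rr <- function(rec, preset = NULL, config = rr_config()) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(preset)) {
    if (is.na(rec$label)) stop("no preset given and recording has no label")
    preset <- preset_for_label(rec$label)
  } else if (is.character(preset)) preset <- activity_preset(preset)
  fs <- rec$fs
  t0 <- rec$thorax$t[1]

  rel <- stage("referencing", list(
    thorax = relative_series(rec$thorax, rec$reference),
    abdomen = relative_series(rec$abdomen, rec$reference)))
  comp <- stage("baseline", lapply(rel, remove_baseline,
                                   window = config$baseline_window))
  pc <- stage("pca", lapply(comp, extract_pc1))

  thr <- stage("threshold", list(
    thorax = compute_threshold(pc$thorax$samples, preset, fs, "thorax", config),
    abdomen = compute_threshold(pc$abdomen$samples, preset, fs, "abdomen", config)))
  f_thresh_m <- merge_thresholds(thr$thorax, thr$abdomen)

  # spectrum analysis and band-pass act on the dimension-reduction output:
  # the 31-sample smoother is only a preliminary for the threshold statistics
  # (its stopband would otherwise erase breathing peaks above ~0.5 Hz)
  peaks <- stage("spectrum", lapply(pc, function(p)
    welch_find_peak(p$samples, f_low = f_thresh_m,
                    f_max = preset$f_search_max, fs = fs,
                    window = config$welch_window,
                    overlap = config$welch_overlap)))
  bands <- stage("band", lapply(peaks, function(p)
    design_bandpass(p$f_peak, f_thresh_m, config$band_delta)))
  bands$sum <- bands$thorax

  filtered <- stage("filter", list(
    thorax = apply_bandpass(pc$thorax$samples, bands$thorax, fs),
    abdomen = apply_bandpass(pc$abdomen$samples, bands$abdomen, fs)))
  filtered$sum <- filtered$thorax + filtered$abdomen
  f_peaks <- list(thorax = peaks$thorax$f_peak, abdomen = peaks$abdomen$f_peak,
                  sum = peaks$thorax$f_peak)
  breaths <- stage("detection", lapply(stats::setNames(names(filtered),
                                                       names(filtered)),
                                       function(nm)
    detect_breaths(filtered[[nm]], f_peaks[[nm]], fs, t0 = t0,
                   config = config)))

  flags <- character(0)
  for (nm in c("thorax", "abdomen"))
    if (peaks[[nm]]$snr < config$snr_ratio)
      flags <- c(flags, paste0("low_snr_", nm))
  for (nm in c("thorax", "abdomen"))
    if (thr[[nm]]$fallback)
      flags <- c(flags, paste0("threshold_fallback_", nm))
  for (nm in names(breaths))
    if (length(breaths[[nm]]$flags))
      flags <- c(flags, paste0(breaths[[nm]]$flags, "_", nm))

  medians <- vapply(breaths, function(b)
    if (length(b$rr_bpm)) stats::median(b$rr_bpm) else NA_real_, numeric(1))

  structure(list(breaths = breaths, median_rr_bpm = medians,
                 thresholds = thr, merged_low_threshold = f_thresh_m,
                 f_peak = unlist(f_peaks), bands = bands,
                 variance_explained = vapply(pc, `[[`, numeric(1),
                                             "variance_explained"),
                 preset = preset$name, flags = flags,
                 label = rec$label, subject_id = rec$subject_id),
            class = "rr_result")
}

#' @export
print.rr_result <- function(x, ...) {
  cat(sprintf("<rr_result> subject=%s  preset=%s\n", x$subject_id, x$preset))
  for (nm in names(x$median_rr_bpm))
    cat(sprintf("  %-7s median RR = %5.1f bpm  (%d breaths, band [%.3f, %.3f] Hz)\n",
                nm, x$median_rr_bpm[[nm]], length(x$breaths[[nm]]$peak_times),
                x$bands[[nm]]$f_L, x$bands[[nm]]$f_U))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Export an RR result
#'
#' Writes the breath table as CSV (`compartment,breath_index,t_peak,rr_bpm`)
#' and a JSON summary (medians, preset, thresholds, flags) next to it.
#'
#' @param result an `rr_result`.
#' @param path output CSV path; the summary goes to `<path>.summary.json`.
#' @return `path`, invisibly.
#' @export
write_rr_result <- function(result, path) {
  stopifnot(inherits(result, "rr_result"))
  rows <- do.call(rbind, lapply(names(result$breaths), function(nm) {
    b <- result$breaths[[nm]]
    k <- length(b$rr_bpm)
    if (!k) return(NULL)
    data.frame(compartment = nm, breath_index = seq_len(k),
               t_peak = b$peak_times[-1], rr_bpm = b$rr_bpm)
  }))
  if (is.null(rows))
    rows <- data.frame(compartment = character(0), breath_index = integer(0),
                       t_peak = numeric(0), rr_bpm = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  summary <- list(subject_id = result$subject_id, label = result$label,
                  preset = result$preset,
                  median_rr_bpm = as.list(result$median_rr_bpm),
                  merged_low_threshold_hz = result$merged_low_threshold,
                  f_peak_hz = as.list(result$f_peak),
                  flags = result$flags)
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
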