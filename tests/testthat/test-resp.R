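test_that("baseline removal matches the brute-force moving average", {
  set.seed(21)
  t <- (0:499) / 10
  m <- cbind(sin(2 * pi * 0.25 * t) + 0.3, rnorm(500), cos(2 * pi * 0.1 * t),
             rnorm(500, sd = 0.1))
  out <- remove_baseline(m, window = 97)
  for (k in 1:4) {
    expected <- m[, k] - moving_average_oracle(m[, k], 97)
    expect_equal(out[, k], expected, tolerance = 1e-12)
  }
})

test_that("a constant series has zero residual after baseline removal", {
  m <- matrix(rep(c(0.5, 0.5, 0.5, 0.5), each = 200), 200, 4)
  expect_equal(max(abs(remove_baseline(m))), 0)
})

test_that("baseline removal rejects short input", {
  expect_error(remove_baseline(matrix(rnorm(200), 50, 4)),
               "insufficient data")
})

test_that("PC1 matches an independent eigen-decomposition", {
  set.seed(22)
  m <- matrix(rnorm(2000), 500, 4) %*% matrix(rnorm(16), 4, 4)
  pc <- extract_pc1(m)
  ev <- eigen(stats::cov(m), symmetric = TRUE)
  proj <- scale(m, center = TRUE, scale = FALSE) %*% ev$vectors[, 1]
  if (sum(proj * pc$samples) < 0) proj <- -proj
  expect_equal(pc$samples, as.numeric(proj), tolerance = 1e-8)
  expect_equal(pc$variance_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-10)
})

test_that("PC1 of a one-dimensional signal is that signal", {
  s <- sin(2 * pi * 0.25 * (0:299) / 10)
  pc <- extract_pc1(cbind(s, 0, 0, 0))
  expect_equal(pc$variance_explained, 1)
  expect_gt(stats::cor(pc$samples, s), 0.999999)
  expect_error(extract_pc1(matrix(1, 100, 4)), "degenerate")
})

test_that("threshold follows max(f_thresh_min, f_mean - f_std)", {
  static <- activity_preset("static")
  walking <- activity_preset("walking")
  expect_equal(threshold_from_stats(0.3, 0.1, static)$f_thresh, 0.2)
  expect_equal(threshold_from_stats(0.25, 0.24, walking)$f_thresh, 0.2)
  expect_equal(threshold_from_stats(0.5, 0.05, walking)$f_thresh, 0.45)
})

test_that("threshold statistics recover a clean sinusoid's frequency", {
  x <- sin(2 * pi * 0.25 * (0:1199) / 10)
  est <- compute_threshold(x, activity_preset("static"))
  expect_lt(abs(est$f_mean - 0.25), 0.25 - 10 / 41)  # one sample-quantization step
  expect_lt(est$f_std, 0.01)
  expect_false(est$fallback)
})

test_that("too few peaks fall back to the preset floor with a flag", {
  est <- compute_threshold(seq_len(200) / 10, activity_preset("running"))
  expect_true(est$fallback)
  expect_equal(est$f_thresh, 0.4)
})

test_that("merged threshold is the minimum of the compartments", {
  p <- activity_preset("static")
  mk <- function(f) threshold_from_stats(f + 0.1, 0.1, p)
  expect_equal(merge_thresholds(mk(0.20), mk(0.15)), 0.15)
  expect_equal(merge_thresholds(mk(0.05), mk(0.05)), 0.05)
  set.seed(23)
  for (i in 1:20) {
    a <- mk(runif(1, 0.05, 1))
    b <- mk(runif(1, 0.05, 1))
    expect_lte(merge_thresholds(a, b), min(a$f_thresh, b$f_thresh))
  }
})

test_that("Welch PSD equals an independent averaged periodogram", {
  set.seed(24)
  x <- sin(2 * pi * 0.25 * (0:499) / 10) + rnorm(500, sd = 0.3)
  mine <- welch_psd(x, fs = 10, window = 300, overlap = 50)
  oracle <- welch_oracle(x, fs = 10, win = 300, ov = 50)
  expect_equal(mine$freq, oracle$freq)
  expect_equal(mine$psd, oracle$psd, tolerance = 1e-8)
})

test_that("the spectral peak of a pure sinusoid is located to one bin", {
  x <- sin(2 * pi * 0.25 * (0:5999) / 10)
  pk <- welch_find_peak(x, 0.05, 1.0)
  expect_lt(abs(pk$f_peak - 0.25), 10 / 300 + 1e-12)
})

test_that("the search band excludes out-of-band artifacts", {
  t <- (0:5999) / 10
  x <- 5 * sin(2 * pi * 0.05 * t) + 0.5 * sin(2 * pi * 0.4 * t)
  pk <- welch_find_peak(x, 0.2, 0.75)
  expect_lt(abs(pk$f_peak - 0.4), 10 / 300 + 1e-12)
  expect_error(welch_find_peak(x, 0.8, 0.75), "band error")
  expect_error(welch_psd(rnorm(100)), "insufficient data")
})

test_that("band edges follow the +/- 0.04 Hz rule with the merged floor", {
  b <- design_bandpass(0.25, 0.20)
  expect_equal(b$f_U, 0.29)
  expect_equal(b$f_L, 0.21)
  b2 <- design_bandpass(0.22, 0.20)
  expect_equal(b2$f_L, 0.20)
  expect_equal(b2$f_U, 0.26)
  expect_error(design_bandpass(0.10, 0.20), "degenerate band")
})

test_that("the band-pass keeps the center and rejects distant tones", {
  t <- (0:5999) / 10
  band <- design_bandpass(0.25, 0.20)
  inb <- sin(2 * pi * 0.25 * t)
  out <- apply_bandpass(inb, band)
  mid <- 1000:5000
  expect_lt(abs(sqrt(mean(out[mid]^2)) / sqrt(mean(inb[mid]^2)) - 1), 0.05)
  far <- sin(2 * pi * 1.5 * t)
  expect_lt(sqrt(mean(apply_bandpass(far, band)^2)) / sqrt(mean(far^2)), 0.05)
  expect_equal(max(abs(apply_bandpass(numeric(6000), band))), 0)
})

test_that("breath detection counts a clean sinusoid's cycles", {
  t <- (0:599) / 10
  bt <- detect_breaths(sin(2 * pi * 0.25 * t), f_peak = 0.25)
  expect_true(abs(length(bt$peak_times) - 15) <= 1)
  expect_true(all(bt$rr_bpm >= 14 & bt$rr_bpm <= 16))
})

test_that("jitter below the prominence floor does not add breaths", {
  t <- (0:599) / 10
  clean <- sin(2 * pi * 0.25 * t)
  jittery <- clean + 0.05 * sin(2 * pi * 2.3 * t)
  n_clean <- length(detect_breaths(clean, 0.25)$peak_times)
  n_jit <- length(detect_breaths(jittery, 0.25)$peak_times)
  expect_equal(n_jit, n_clean)
})

test_that("a flat signal yields an empty, flagged breath table", {
  bt <- detect_breaths(numeric(600), f_peak = 0.25)
  expect_length(bt$peak_times, 0)
  expect_true("no_peaks" %in% bt$flags)
})

test_that("a simulated static recording is recovered within 1 breath/min", {
  sim <- simulate_recording(scenario("sitting_no_support", rr_bpm = 15,
                                     seed = 31))
  res <- estimate_rr(sim$recording, "static")
  for (nm in c("thorax", "abdomen", "sum"))
    expect_lt(abs(res$median_rr_bpm[[nm]] - 15), 1)
})

test_that("median RR always lies inside the fitted band", {
  for (cfg in list(list("standing", 14, "static", 32),
                   list("walking_4kmh", 24, "walking", 33),
                   list("running", 40, "running", 34))) {
    sim <- simulate_recording(scenario(cfg[[1]], rr_bpm = cfg[[2]],
                                       seed = cfg[[4]]))
    res <- estimate_rr(sim$recording, cfg[[3]])
    for (nm in names(res$median_rr_bpm)) {
      b <- res$bands[[nm]]
      expect_gte(res$median_rr_bpm[[nm]], 60 * b$f_L - 1e-9)
      expect_lte(res$median_rr_bpm[[nm]], 60 * b$f_U + 1e-9)
    }
  }
})

test_that("the pipeline is deterministic on identical input", {
  sim <- simulate_recording(scenario("cycling", rr_bpm = 24, seed = 35))
  r1 <- estimate_rr(sim$recording, "cycling")
  r2 <- estimate_rr(sim$recording, "cycling")
  expect_identical(r1, r2)
})

test_that("estimated medians increase with the true rate", {
  grid <- list(list(12, "standing", "static"), list(15, "standing", "static"),
               list(20, "standing", "static"), list(30, "walking_4kmh", "walking"),
               list(40, "running", "running"), list(50, "running", "running"))
  est <- vapply(seq_along(grid), function(i) {
    g <- grid[[i]]
    sim <- simulate_recording(scenario(g[[2]], rr_bpm = g[[1]], seed = 40 + i))
    estimate_rr(sim$recording, g[[3]])$median_rr_bpm[["sum"]]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("a band that excludes the true rate degrades the estimate visibly", {
  sim <- simulate_recording(scenario("running", rr_bpm = 50, seed = 36))
  matched <- estimate_rr(sim$recording, "running")
  expect_lt(abs(matched$median_rr_bpm[["sum"]] - 50), 2)
  mismatched <- estimate_rr(sim$recording, "walking")  # ceiling 0.75 Hz < 0.83 Hz
  expect_true(length(mismatched$flags) > 0 ||
                abs(mismatched$median_rr_bpm[["sum"]] - 50) > 5)
})

test_that("recordings shorter than one Welch window fail in the spectrum stage", {
  sim <- simulate_recording(scenario("standing", duration = 20,
                                     dropout_rate = 0, seed = 37))
  expect_error(estimate_rr(sim$recording, "static"), "spectrum stage")
})

test_that("breath tables and summaries export to disk", {
  sim <- simulate_recording(scenario("standing", rr_bpm = 15, seed = 38))
  res <- estimate_rr(sim$recording, "static")
  path <- withr::local_tempfile(fileext = ".csv")
  write_rr_result(res, path)
  tab <- read.csv(path)
  expect_named(tab, c("compartment", "breath_index", "t_peak", "rr_bpm"))
  expect_setequal(unique(tab$compartment), c("thorax", "abdomen", "sum"))
  summ <- jsonlite::read_json(paste0(path, ".summary.json"))
  expect_equal(summ$preset, "static")
  expect_equal(summ$median_rr_bpm$sum, res$median_rr_bpm[["sum"]],
               tolerance = 1e-12)
})
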