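make_flat_recording <- function(n, label, subject = "s1", seed = 1) {
  set.seed(seed)
  q <- quat_normalize(matrix(rnorm(4 * n, mean = rep(c(1, 0, 0, 0), each = n),
                                   sd = 0.01), n, 4))
  recording(make_series(q, "thorax"), make_series(q, "abdomen"),
            make_series(q, "reference"), label = label, subject_id = subject)
}

test_that("segmentation yields non-overlapping 200-sample windows", {
  ds <- segment_windows(make_flat_recording(2000, "standing"), units = "all")
  expect_length(ds$windows, 10)
  expect_true(all(vapply(ds$windows, nrow, integer(1)) == 200))
  expect_equal(ncol(ds$windows[[1]]), 12)
  ds2 <- segment_windows(make_flat_recording(2100, "standing"))
  expect_length(ds2$windows, 10)  # 100-sample remainder dropped
  expect_warning(segment_windows(make_flat_recording(150, "standing")),
                 "shorter than one window")
})

test_that("segmentation conserves samples up to the dropped remainder", {
  corpus <- list(make_flat_recording(2100, "standing"),
                 make_flat_recording(950, "running", seed = 2))
  ds <- segment_windows(corpus)
  expect_equal(length(ds$windows) * 200 + (2100 %% 200) + (950 %% 200),
               2100 + 950)
})

test_that("task labels merge to the ten activity classes", {
  expect_equal(merge_activity_label(c("walking_4kmh", "walking_6kmh")),
               c("walking", "walking"))
  expect_equal(merge_activity_label(c("sitting_support", "sitting_no_support")),
               c("sitting", "sitting"))
  expect_equal(merge_activity_label("cycling"), "cycling")
  ds <- segment_windows(make_flat_recording(400, "walking_6kmh"))
  expect_true(all(ds$labels == "walking"))
})

test_that("standardization centers and scales with the population sd", {
  ds <- segment_windows(make_flat_recording(400, "standing"), units = "reference")
  # overwrite one channel with known values: alternating 1 and 3
  ds$windows <- lapply(ds$windows, function(w) {
    w[, 2] <- rep(c(1, 3), length.out = nrow(w)); w
  })
  std <- standardize_windows(ds)$dataset
  vals <- unique(round(std$windows[[1]][, 2], 12))
  expect_setequal(vals, c(-1, 1))
  all_data <- do.call(rbind, std$windows)
  expect_lt(max(abs(colMeans(all_data))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(all_data, 2, colMeans(all_data))^2)) - 1)),
            1e-9)
  # idempotence
  std2 <- standardize_windows(std)$dataset
  expect_equal(do.call(rbind, std2$windows), all_data, tolerance = 1e-9)
})

test_that("constant channels standardize to zero with a warning", {
  ds <- segment_windows(make_flat_recording(400, "standing"), units = "reference")
  ds$windows <- lapply(ds$windows, function(w) { w[, 3] <- 2; w })
  expect_warning(std <- standardize_windows(ds), "constant channel")
  expect_true(all(std$dataset$windows[[1]][, 3] == 0))
})

test_that("time features match hand arithmetic on a tiny window", {
  ds <- list(windows = list(matrix(c(1, 2, 3, 4), 4, 1,
                                   dimnames = list(NULL, "reference_w"))),
             labels = "standing", subjects = "s1",
             channels = "reference_w", window_length = 4)
  class(ds) <- "windowed_dataset"
  f <- extract_features(ds)
  expect_equal(f$reference_w_mean, 2.5)
  expect_equal(f$reference_w_p2p, 3)
  expect_equal(f$reference_w_median, 2.5)
  expect_equal(f$reference_w_iqr, 1.5)  # linear-interpolation quartiles
  expect_equal(f$reference_w_var, var(1:4))
})

test_that("feature column counts match the channel configurations", {
  rec <- make_flat_recording(400, "standing")
  one <- extract_features(segment_windows(rec, units = "reference"),
                          include_frequency = TRUE)
  expect_length(quatresp:::feature_columns(one), 60)   # 4 channels x 15
  three <- extract_features(segment_windows(rec, units = "all"))
  expect_length(quatresp:::feature_columns(three), 96) # 12 channels x 8
})

test_that("an in-window sinusoid dominates its FFT features", {
  n <- 200
  x <- sin(2 * pi * 10 * (0:(n - 1)) / n)  # exactly bin 10
  ds <- list(windows = list(matrix(x, n, 1, dimnames = list(NULL, "c1"))),
             labels = "standing", subjects = "s1", channels = "c1",
             window_length = n)
  class(ds) <- "windowed_dataset"
  f <- extract_features(ds, include_frequency = TRUE)
  mag <- Mod(stats::fft(x))[2:(n / 2 + 1)]   # direct DFT oracle
  expect_equal(f$c1_fft_max, max(mag), tolerance = 1e-10)
  expect_gt(f$c1_fft_max, 10 * f$c1_fft_mean)
  expect_equal(f$c1_fft_min, min(mag), tolerance = 1e-10)
})

test_that("degenerate windows get defined moment fallbacks", {
  ds <- list(windows = list(matrix(1, 8, 1, dimnames = list(NULL, "c1"))),
             labels = "standing", subjects = "s1", channels = "c1",
             window_length = 8)
  class(ds) <- "windowed_dataset"
  f <- extract_features(ds, include_frequency = TRUE)
  expect_true(all(is.finite(as.matrix(f[quatresp:::feature_columns(f)]))))
  expect_equal(f$c1_kurtosis, 0)
  expect_equal(f$c1_skewness, 0)
})

make_cluster_features <- function(n_per = 50, seed = 44) {
  set.seed(seed)
  f <- data.frame(f1 = c(rnorm(n_per, 0), rnorm(n_per, 20)),
                  f2 = c(rnorm(n_per, 0), rnorm(n_per, 20)),
                  label = rep(c("a", "b"), each = n_per),
                  subject = "s1")
  class(f) <- c("feature_table", "data.frame")
  f
}

test_that("balancing downsamples every class to the minimum count", {
  f <- make_cluster_features()
  f <- rbind(f, f[f$label == "a", ][1:30, ])  # unbalance: a=80, b=50
  class(f) <- c("feature_table", "data.frame")
  split <- prepare_dataset(f, balance = TRUE, seed = 42)
  counts <- table(c(split$train$label, split$test$label))
  expect_true(all(counts == 50))
  expect_equal(nrow(split$train), 80)
  expect_equal(nrow(split$test), 20)
})

test_that("the split is seed-reproducible and seed-sensitive", {
  f <- make_cluster_features()
  s1 <- prepare_dataset(f, seed = 42)
  s2 <- prepare_dataset(f, seed = 42)
  s3 <- prepare_dataset(f, seed = 43)
  expect_identical(s1$train_idx, s2$train_idx)
  expect_false(identical(s1$train_idx, s3$train_idx))
  expect_length(s1$train_idx, 80)
})

test_that("classes with fewer than 2 windows are a configuration error", {
  f <- make_cluster_features()
  f <- rbind(f, data.frame(f1 = 0, f2 = 0, label = "c", subject = "s1"))
  expect_error(prepare_dataset(f), "configuration error.*c")
})

test_that("the RBF kernel follows its closed form", {
  expect_equal(rbf_kernel(c(0, 0), c(0, 0)), 1)
  expect_equal(rbf_kernel(c(0, 0), c(2, 0)), exp(-2))  # squared distance 4
  expect_equal(rbf_kernel(1, 3, sigma = 2), exp(-4 / 8))
})

test_that("all models separate well-separated clusters perfectly", {
  split <- prepare_dataset(make_cluster_features(), seed = 42)
  for (m in c("knn", "rf", "svm")) {
    met <- train_and_evaluate(split, model = m)
    expect_equal(met$accuracy, 1.0)
    expect_equal(met$f1, 1.0)
  }
})

test_that("metrics of perfect predictions are exactly one", {
  y <- factor(rep(c("a", "b", "c"), 10))
  met <- eval_metrics(y, y)
  expect_equal(met$accuracy, 1)
  expect_equal(met$precision, 1)
  expect_equal(met$recall, 1)
  expect_equal(met$f1, 1)
  expect_true(all(met$confusion[lower.tri(met$confusion)] == 0,
                  met$confusion[upper.tri(met$confusion)] == 0))
})

test_that("test classes unseen in training raise an evaluation error", {
  f <- make_cluster_features()
  split <- prepare_dataset(f, seed = 42)
  split$test$label[1] <- "ghost"
  expect_error(train_and_evaluate(split, model = "knn"),
               "evaluation error.*ghost")
})
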