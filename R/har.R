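#' Human activity recognition from quaternion windows
#'
#' Raw quaternion channels (four components per unit; the reference unit
#' alone or all three units) are standardized, segmented into non-overlapping
#' 200-sample windows (20 s at 10 Hz), summarized by time-domain and
#' optionally frequency-domain features, optionally balanced by downsampling
#' to the smallest class, split 80/20, and classified with k-nearest
#' neighbours (k = 5, Euclidean), random forest (Gini splitting), or an RBF
#' support vector machine (sigma = 1).
#'
#' @name har-pipeline
NULL

HAR_CLASSES <- c("cycling", "lying_left", "lying_right", "prone", "running",
                 "sitting", "stairs", "standing", "supine", "walking")

TIME_FEATURES <- c("mean", "sd", "var", "kurtosis", "skewness", "p2p",
                   "median", "iqr")
FREQ_FEATURES <- c("fft_mean", "fft_sd", "fft_skewness", "fft_max", "fft_min",
                   "psd_mean", "psd_max")

#' Merge protocol task labels into the ten activity classes
#'
#' Sitting with and without back support merge into `sitting`; walking at
#' 4 and 6 km/h merge into `walking`; other tasks keep their name.
#'
#' @param label character vector of task labels.
#' @return Character vector of merged class labels.
#' @export
merge_activity_label <- function(label) {
  out <- label
  out[label %in% c("sitting_support", "sitting_no_support")] <- "sitting"
  out[label %in% c("walking_4kmh", "walking_6kmh")] <- "walking"
  out
}

corpus_channels <- function(rec, units) {
  sel <- if (units == "reference") "reference" else VALID_UNITS
  m <- do.call(cbind, lapply(sel, function(u) {
    q <- rec[[u]]$q
    colnames(q) <- paste(u, c("w", "x", "y", "z"), sep = "_")
    q
  }))
  m
}

#' Segment recordings into fixed-length labeled windows
#'
#' Non-overlapping contiguous windows; a trailing remainder shorter than one
#' window is dropped, and recordings shorter than one window are skipped
#' with a warning. Labels are inherited from each recording after merging.
#'
#' @param corpus a `recording` or a list of them.
#' @param length window length in samples (default 200 = 20 s at 10 Hz).
#' @param units `"all"` for the twelve channels of the three units,
#'   `"reference"` for the four reference-unit channels.
#' @return A `windowed_dataset`: list with `windows` (list of
#'   `length` x channels matrices), `labels`, `subjects`, `channels`.
#' @export
segment_windows <- function(corpus, length = 200, units = c("all", "reference")) {
  units <- match.arg(units)
  if (inherits(corpus, "recording")) corpus <- list(corpus)
  windows <- list()
  labels <- character(0)
  subjects <- character(0)
  channels <- NULL
  for (rec in corpus) {
    m <- corpus_channels(rec, units)
    if (is.null(channels)) channels <- colnames(m)
    k <- nrow(m) %/% length
    if (k == 0L) {
      warning("recording ", rec$subject_id, "/", rec$label,
              " shorter than one window; skipped")
      next
    }
    lab <- merge_activity_label(rec$label)
    for (i in seq_len(k)) {
      windows[[base::length(windows) + 1L]] <-
        m[((i - 1L) * length + 1L):(i * length), , drop = FALSE]
      labels <- c(labels, lab)
      subjects <- c(subjects, rec$subject_id)
    }
  }
  structure(list(windows = windows, labels = labels, subjects = subjects,
                 channels = channels, window_length = length),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows x %d samples x %d channels, %d classes\n",
              length(x$windows), x$window_length, length(x$channels),
              length(unique(x$labels))))
  invisible(x)
}

#' Standardize a windowed dataset per channel
#'
#' Fits a per-channel mean and standard deviation over the whole dataset and
#' applies `(x - mu) / sigma`. Constant channels (`sigma = 0`) are emitted as
#' all zeros and flagged with a warning. Fitting over the whole dataset
#' (before the train/test split) follows the stated preprocessing order of
#' the original pipeline; pass `params` fitted on a training subset for a
#' leakage-free variant.
#'
#' @param dataset a `windowed_dataset`.
#' @param params optional precomputed standardization parameters (list with
#'   `mu`, `sigma`) to apply instead of fitting.
#' @return A list with `dataset` (standardized) and `params` (list `mu`,
#'   `sigma`, `constant_channels`).
#' @export
standardize_windows <- function(dataset, params = NULL) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  all_data <- do.call(rbind, dataset$windows)
  if (is.null(params)) {
    mu <- colMeans(all_data)
    # population (1/n) standard deviation, as in the usual ML scaler
    sigma <- sqrt(colMeans(sweep(all_data, 2, mu, "-")^2))
    params <- list(mu = mu, sigma = sigma,
                   constant_channels = dataset$channels[sigma == 0])
  }
  if (length(params$constant_channels))
    warning("constant channel(s) standardized to zero: ",
            paste(params$constant_channels, collapse = ", "))
  sigma_safe <- ifelse(params$sigma == 0, 1, params$sigma)
  dataset$windows <- lapply(dataset$windows, function(w) {
    w <- sweep(w, 2, params$mu, "-")
    w <- sweep(w, 2, sigma_safe, "/")
    w[, params$sigma == 0] <- 0
    w
  })
  list(dataset = dataset, params = params)
}

safe_moment <- function(f, x) {
  v <- f(x)
  if (!is.finite(v)) 0 else v
}

window_features <- function(w, channels, include_frequency, fs = 10) {
  feats <- numeric(0)
  nms <- character(0)
  n <- nrow(w)
  for (j in seq_along(channels)) {
    x <- w[, j]
    tf <- c(mean(x), stats::sd(x), stats::var(x),
            safe_moment(e1071::kurtosis, x), safe_moment(e1071::skewness, x),
            max(x) - min(x), stats::median(x),
            stats::IQR(x, type = 7))
    feats <- c(feats, tf)
    nms <- c(nms, paste(channels[j], TIME_FEATURES, sep = "_"))
    if (include_frequency) {
      mag <- Mod(stats::fft(x))[2:(n %/% 2 + 1)]   # one-sided, DC excluded
      psd <- mag^2 / (n * fs)
      ff <- c(mean(mag), stats::sd(mag), safe_moment(e1071::skewness, mag),
              max(mag), min(mag), mean(psd), max(psd))
      feats <- c(feats, ff)
      nms <- c(nms, paste(channels[j], FREQ_FEATURES, sep = "_"))
    }
  }
  stats::setNames(feats, nms)
}

#' Extract per-window, per-channel features
#'
#' Eight time-domain features per channel (mean, standard deviation,
#' variance, kurtosis, skewness, peak-to-peak distance, median,
#' interquartile range with the linear-interpolation quartile rule) and,
#' optionally, seven frequency-domain features from the window's FFT (mean,
#' standard deviation, skewness, maximum and minimum of the one-sided
#' magnitude spectrum excluding the zero-frequency bin; mean and maximum of
#' the power spectral density). Kurtosis and skewness of a constant window
#' are defined as 0.
#'
#' @param dataset a (standardized) `windowed_dataset`.
#' @param include_frequency add the frequency-domain features.
#' @param fs sampling rate in Hz (PSD scaling only).
#' @return A `feature_table` data frame: one row per window, feature columns
#'   in fixed order (per channel: time features, then frequency features),
#'   plus `label` and `subject`.
#' @export
extract_features <- function(dataset, include_frequency = FALSE, fs = 10) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  rows <- t(vapply(dataset$windows, window_features,
                   numeric((8L + 7L * include_frequency) * length(dataset$channels)),
                   channels = dataset$channels,
                   include_frequency = include_frequency, fs = fs))
  out <- as.data.frame(rows)
  out$label <- dataset$labels
  out$subject <- dataset$subjects
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function(features)
  setdiff(names(features), c("label", "subject"))

#' Balance classes and split into training and test sets
#'
#' With `balance = TRUE`, every class is downsampled (uniformly, without
#' replacement) to the size of the smallest class; windows are never
#' duplicated. A non-stratified random split then assigns `train_fraction`
#' of the rows to the training set. Both draws are driven by `seed`, so the
#' split is bit-reproducible.
#'
#' @param features a `feature_table` from [extract_features()].
#' @param balance downsample all classes to the minimum class count.
#' @param train_fraction fraction of rows used for training (default 0.8).
#' @param seed random seed (default 42).
#' @return A list with `train` and `test` data frames and the row indices
#'   (`train_idx`, `test_idx`) into the post-balancing table.
#' @export
prepare_dataset <- function(features, balance = FALSE, train_fraction = 0.8,
                            seed = 42) {
  counts <- table(features$label)
  if (any(counts < 2))
    stop("configuration error: class(es) with fewer than 2 windows: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  set.seed(seed)
  if (balance) {
    m <- min(counts)
    keep <- unlist(lapply(split(seq_len(nrow(features)), features$label),
                          function(ix) sort(sample(ix, m))),
                   use.names = FALSE)
    features <- features[sort(keep), , drop = FALSE]
  }
  n <- nrow(features)
  train_idx <- sort(sample.int(n, floor(train_fraction * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = features[train_idx, , drop = FALSE],
       test = features[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Radial basis function kernel
#'
#' `K(x1, x2) = exp(-||x1 - x2||^2 / (2 sigma^2))`: 1 at distance zero,
#' decaying with the squared Euclidean distance.
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param sigma kernel bandwidth (default 1).
#' @return The kernel value.
#' @export
rbf_kernel <- function(x1, x2, sigma = 1) {
  stopifnot(sigma > 0)
  exp(-sum((x1 - x2)^2) / (2 * sigma^2))
}

#' Train a classifier and evaluate it on the test set
#'
#' Models: `knn` (k = 5, Euclidean metric), `rf` (random forest with the
#' Gini splitting criterion), `svm` (RBF kernel, bandwidth `sigma = 1`,
#' i.e. `gamma = 1/(2 sigma^2)`). Returns accuracy, macro-averaged
#' precision, recall and F1 (undefined per-class ratios counted as 0), and
#' the confusion matrix (rows = truth, columns = prediction).
#'
#' @param split output of [prepare_dataset()].
#' @param model one of `"knn"`, `"rf"`, `"svm"`.
#' @param k neighbours for KNN.
#' @param sigma RBF bandwidth for the SVM.
#' @param ntree trees for the random forest.
#' @param seed seed for the (stochastic) random forest fit.
#' @return An `eval_metrics` object: list with `model`, `accuracy`,
#'   `precision`, `recall`, `f1`, `confusion`.
#' @export
train_and_evaluate <- function(split, model = c("knn", "rf", "svm"), k = 5,
                               sigma = 1, ntree = 500, seed = 42) {
  model <- match.arg(model)
  cols <- feature_columns(split$train)
  xtr <- as.matrix(split$train[cols])
  xte <- as.matrix(split$test[cols])
  ytr <- factor(split$train$label)
  unseen <- setdiff(unique(split$test$label), levels(ytr))
  if (length(unseen))
    stop("evaluation error: test class(es) absent from training set: ",
         paste(unseen, collapse = ", "))
  yte <- factor(split$test$label, levels = levels(ytr))
  pred <- switch(model,
    knn = class::knn(xtr, xte, ytr, k = k),
    rf = {
      set.seed(seed)
      fit <- randomForest::randomForest(x = xtr, y = ytr, ntree = ntree)
      stats::predict(fit, xte)
    },
    svm = {
      fit <- e1071::svm(x = xtr, y = ytr, kernel = "radial",
                        gamma = 1 / (2 * sigma^2), scale = FALSE)
      stats::predict(fit, xte)
    })
  eval_metrics(yte, factor(pred, levels = levels(ytr)), model)
}

#' Classification metrics from truth and prediction
#'
#' @param truth,pred factors over the same level set.
#' @param model model name stored in the result.
#' @return An `eval_metrics` object.
#' @export
eval_metrics <- function(truth, pred, model = "custom") {
  stopifnot(identical(levels(truth), levels(pred)))
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  prec <- tp / colSums(cm)
  rec <- tp / rowSums(cm)
  f1 <- 2 * prec * rec / (prec + rec)
  prec[!is.finite(prec)] <- 0
  rec[!is.finite(rec)] <- 0
  f1[!is.finite(f1)] <- 0
  structure(list(model = model,
                 accuracy = sum(tp) / sum(cm),
                 precision = mean(prec), recall = mean(rec), f1 = mean(f1),
                 confusion = cm),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> %s: accuracy=%.3f precision=%.3f recall=%.3f F1=%.3f\n",
              x$model, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Run the full HAR pipeline on a corpus of recordings
#'
#' Segmentation, standardization, feature extraction, optional balancing,
#' seeded 80/20 split, and evaluation of the requested models. Defaults
#' follow the study configuration: the single-unit (reference) run uses
#' time + frequency features and keeps the class imbalance; the three-unit
#' run uses time features only and balances the classes.
#'
#' @param corpus list of `recording` objects.
#' @param units `"all"` or `"reference"`.
#' @param models character vector over `"knn"`, `"rf"`, `"svm"`.
#' @param include_frequency default: `TRUE` for the single-unit
#'   configuration, `FALSE` for three units.
#' @param balance default: `FALSE` for the single-unit configuration,
#'   `TRUE` for three units.
#' @param seed split / model seed.
#' @return Named list of `eval_metrics`, one per model, with the feature
#'   table attached as attribute `features`.
#' @export
har_pipeline <- function(corpus, units = c("all", "reference"),
                         models = c("knn", "rf", "svm"),
                         include_frequency = NULL, balance = NULL,
                         seed = 42) {
  units <- match.arg(units)
  if (is.null(include_frequency)) include_frequency <- units == "reference"
  if (is.null(balance)) balance <- units == "all"
  ds <- segment_windows(corpus, units = units)
  std <- standardize_windows(ds)
  features <- extract_features(std$dataset, include_frequency = include_frequency)
  split <- prepare_dataset(features, balance = balance, seed = seed)
  out <- lapply(stats::setNames(models, models), function(m)
    train_and_evaluate(split, model = m, seed = seed))
  attr(out, "features") <- features
  out
}
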