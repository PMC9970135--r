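# shared fixtures, built in code

rand_unit_quat <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m / sqrt(rowSums(m^2))
}

make_series <- function(q, unit = "thorax", fs = 10) {
  q <- if (is.matrix(q)) q else matrix(q, ncol = 4, byrow = TRUE)
  quat_series((seq_len(nrow(q)) - 1) / fs, q, unit, fs = fs)
}

# a tiny hand-written log: 5 samples per unit, one counter gap (17 -> 19)
# in the thorax
write_tiny_log <- function(path, gap = FALSE) {
  rows <- c("subject_id,unit_id,counter,t,qw,qx,qy,qz")
  for (u in c("thorax", "abdomen", "reference")) {
    counters <- 15:19
    times <- (0:4) / 10
    if (gap && u == "thorax") {
      counters <- c(15, 16, 17, 19)
      times <- c(0, 0.1, 0.2, 0.4)
    }
    rows <- c(rows, sprintf("s1,%s,%d,%s,1,0,0,0", u, counters, times))
  }
  writeLines(rows, path)
  path
}

# independent segment-averaged periodogram (Hamming taper), written as a
# plain loop so it cannot share code with welch_psd()
welch_oracle <- function(x, fs = 10, win = 300, ov = 50) {
  step <- win - ov
  starts <- seq(1, length(x) - win + 1, by = step)
  h <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  u <- fs * sum(h^2)
  nf <- win %/% 2 + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + win - 1)]
    seg <- (seg - mean(seg)) * h
    p <- (Mod(stats::fft(seg))^2 / u)[1:nf]
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    acc <- acc + p
  }
  list(freq = (0:(nf - 1)) * fs / win, psd = acc / length(starts))
}

# brute-force centered moving average with symmetric edge shrink
moving_average_oracle <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    mean(x[(i - k):(i + k)])
  }, numeric(1))
}
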