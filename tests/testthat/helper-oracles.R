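# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each operation so they share no
# code path with the package implementation.

# O(N^2) discrete Fourier transform by explicit summation
dft_naive <- function(x, inverse = FALSE) {
  n <- length(x)
  sgn <- if (inverse) 2i else -2i
  vapply(seq_len(n) - 1, function(k) {
    sum(x * exp(sgn * pi * k * (seq_len(n) - 1) / n))
  }, complex(1))
}

# full reference-channel suppression by naive DFT, elementwise formula
# application, and naive inverse DFT
spectral_suppress_naive <- function(s1, s2) {
  X1 <- dft_naive(s1)
  X2 <- dft_naive(s2)
  SF <- exp(-Mod(X2) / mean(Mod(X1)))
  Xs <- SF * X1
  Re(dft_naive(Xs, inverse = TRUE)) / length(s1)
}

# sliding median with reflected edges, one window at a time
median_naive <- function(x, k) {
  h <- k %/% 2
  n <- length(x)
  xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  vapply(seq_len(n), function(i) median(xp[i:(i + k - 1)]), numeric(1))
}

# window starts by explicit enumeration
enumerate_starts <- function(N, L, step) {
  starts <- integer(0)
  s <- 0L
  while (s + L <= N) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

# snippet labels by a double loop over windows and peaks
label_naive <- function(starts, L, peaks, tol) {
  vapply(starts, function(s) {
    center <- s + (L - 1) / 2
    for (p in peaks) {
      if (abs(p - center) <= tol) return(1L)
    }
    0L
  }, integer(1))
}

# confusion counts by an explicit loop
confusion_naive <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# dominant periodogram frequency of a trace
peak_frequency <- function(samples, fs) {
  sp <- stats::spec.pgram(stats::ts(samples, frequency = fs), taper = 0,
                          plot = FALSE, detrend = TRUE)
  sp$freq[which.max(sp$spec)]
}

# frequency resolution of the periodogram for a given trace length
freq_bin <- function(n, fs) fs / n

# same-name/rate trace with new samples
trace_with2 <- function(tr, samples) channel_trace(tr$name, samples, tr$fs)

# small labeled snippet set for model tests: class 1 has a bump in the
# window center of every channel, class 0 is noise only
toy_snippet_set <- function(n = 200, n_channels = 2, L = 41, seed = 1,
                            channels = paste0("ch", seq_len(n_channels)),
                            amplitude = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  bump <- amplitude * exp(-((seq_len(L) - (L + 1) / 2)^2) / 8)
  data <- array(stats::rnorm(n * n_channels * L, sd = 0.3),
                c(n, n_channels, L))
  for (i in which(y == 1L)) {
    for (c in seq_len(n_channels)) data[i, c, ] <- data[i, c, ] + bump
  }
  snippet_set(data,
              data.frame(subject_id = "toy", scenario = "city",
                         start = seq_len(n) - 1L),
              channels, fs = 200, labels = y)
}

# compact config for fast model tests
toy_config <- function(...) {
  args <- list(snippet_len = 41L, train_overlap = 30L, test_overlap = 40L,
               filter_len = 10L, pool_size = 2L, epochs = 3L,
               batch_size = 32L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pipeline_config, args)
}
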