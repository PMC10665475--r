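# Dense (full-trace) prediction. For step-1 test windows, consecutive
# snippets share all but one sample, so running the conv branch per
# snippet recomputes almost everything. Instead: convolve each channel's
# full trace once, ReLU, take a width-`pool` running max, and gather each
# window's pooled features from that shared structure. This is exactly
# branch_forward + dense applied window-wise (ReLU commutes with max;
# dropout is off at prediction), verified against predict() in the tests.

# conv over the full trace for one branch: returns (N_pos x nf), ReLU'd
branch_conv_trace <- function(br, channel_samples, hyper) {
  fl <- hyper$filter_len
  N <- length(channel_samples[[1]])
  P <- N - fl + 1L
  A <- matrix(0, P, fl * length(channel_samples))
  for (c in seq_along(channel_samples)) {
    x <- channel_samples[[c]]
    for (j in seq_len(fl)) {
      A[, (c - 1L) * fl + j] <- x[j:(j + P - 1L)]
    }
  }
  Z <- A %*% br$Wc
  Z <- Z + rep(br$bc, each = P)
  Z[Z < 0] <- 0
  Z
}

running_max <- function(Z, width) {
  n <- nrow(Z) - width + 1L
  M <- Z[seq_len(n), , drop = FALSE]
  if (width > 1L) {
    for (w in 2:width) M <- pmax(M, Z[w:(w + n - 1L), , drop = FALSE])
  }
  M
}

# scores for windows starting at `starts0` (0-based) on aligned traces
dense_scores <- function(model, traces, starts0) {
  UseMethod("dense_scores")
}

#' @export
dense_scores.fusion_model <- function(model, traces, starts0) {
  hyper <- model$hyper
  pool <- hyper$pool_size
  nf <- hyper$n_filters
  L <- model$snippet_len
  P <- L - hyper$filter_len + 1L
  nP <- P %/% pool
  n <- length(starts0)
  ord <- model$channel_order
  missing <- setdiff(ord, names(traces))
  if (length(missing)) {
    stop("channel-order mismatch: traces lack [",
         paste(missing, collapse = ", "), "]")
  }
  N <- length(traces[[ord[1]]]$samples)
  if (any(starts0 < 0L) || any(starts0 + L > N)) {
    stop("dense_scores: window exceeds trace length")
  }
  H <- matrix(0, n, model$feat_per_branch * length(model$branches))
  off <- 0L
  for (br in model$branches) {
    ch <- lapply(ord[br$channels], function(nm) traces[[nm]]$samples)
    M <- running_max(branch_conv_trace(br, ch, hyper), pool)
    for (f in seq_len(nf)) {
      for (g in seq_len(nP)) {
        H[, off + (f - 1L) * nP + g] <- M[starts0 + (g - 1L) * pool + 1L, f]
      }
    }
    off <- off + model$feat_per_branch
  }
  stats::plogis(drop(H %*% model$dense$w) + model$dense$b)
}

#' @export
dense_scores.hybrid_model <- function(model, traces, starts0) {
  sapply(model$members, dense_scores, traces = traces, starts0 = starts0)
}

# binary predictions for all test windows of one preprocessed recording
predict_recording_windows <- function(model, rec, config) {
  L <- config$snippet_len
  step <- L - config$test_overlap
  sensors <- if (inherits(model, "hybrid_model")) {
    model$signals
  } else {
    model$channel_order
  }
  N <- min(vapply(rec$channels[sensors], length, integer(1)))
  starts0 <- seq.int(0L, N - L, by = step)
  peaks <- detect_reference_peaks(rec$channels$reference, config)
  centers <- starts0 + (L - 1) / 2
  p <- peaks$indices
  labels <- if (length(p)) {
    as.integer(findInterval(centers + config$label_tolerance, p) >
                 findInterval(centers - config$label_tolerance - 0.5, p))
  } else {
    integer(length(starts0))
  }
  if (inherits(model, "hybrid_model")) {
    S <- dense_scores(model, rec$channels, starts0)
    Y <- majority_vote(as.integer(S[, "early"] >= model$threshold),
                       as.integer(S[, "signal_late"] >= model$threshold),
                       as.integer(S[, "sensor_late"] >= model$threshold))
  } else {
    Y <- as.integer(dense_scores(model, rec$channels, starts0) >=
                      model$threshold)
  }
  list(Y = Y, labels = labels, starts = starts0)
}
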