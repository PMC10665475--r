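#' Breathing-peak train
#'
#' Strictly increasing 0-based sample indices of breathing peaks on a
#' common timeline (time of index `i` is `i / fs` seconds).
#'
#' @param indices Integer vector, strictly increasing, >= 0.
#' @param fs Sampling rate of the timeline in Hz.
#' @return An object of class `peak_train`.
#' @export
peak_train <- function(indices, fs) {
  indices <- as.integer(indices)
  if (length(indices) && (any(diff(indices) <= 0L) || indices[1] < 0L)) {
    stop("peak_train: indices must be strictly increasing and >= 0")
  }
  structure(list(indices = indices, fs = fs), class = "peak_train")
}

#' @export
length.peak_train <- function(x) length(x$indices)

# local maxima with topographic prominence, minimum spacing enforced
# greedily from the highest peak down
find_peaks <- function(x, min_distance, min_prominence) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1L && x[j] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    if (x[j] <= x[i]) lmin <- min(x[seq_len(i)])
    rmin <- x[i]; j <- i
    while (j < n && x[j] <= x[i]) { j <- j + 1L; rmin <- min(rmin, x[j]) }
    if (x[j] <= x[i]) rmin <- min(x[i:n])
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  ord <- keep[order(x[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(chosen - i) >= min_distance)) {
      chosen <- c(chosen, i)
    }
  }
  sort(chosen)
}

#' Detect breathing peaks in the chest-belt reference
#'
#' Local maxima of the reference trace with a minimum spacing of
#' `peak_min_distance_s` seconds (1.5 s caps the rate at 40 breaths/min)
#' and a minimum topographic prominence of `peak_min_prominence` times
#' the interquartile range of the trace, making the threshold scale-free.
#'
#' Before peak picking the trace is smoothed to physiological bandwidth
#' (zero-phase low-pass at 2 Hz, well above any plausible breathing
#' rate), so measurement noise cannot contribute spurious local maxima;
#' zero-phase filtering leaves peak positions unshifted.
#'
#' @param reference A [channel_trace] at the unified rate.
#' @param config A [pipeline_config].
#' @return A [peak_train] (0-based indices). Constant or too-short traces
#'   yield an empty train with a logged warning.
#' @export
detect_reference_peaks <- function(reference, config = pipeline_config()) {
  stopifnot(inherits(reference, "channel_trace"))
  x <- reference$samples
  if (stats::IQR(x) == 0) {
    rf_log("detect_reference_peaks: constant reference; no peaks", force = TRUE)
    return(peak_train(integer(0), reference$fs))
  }
  if (length(x) > 24L && reference$fs > 4) {
    lp <- signal::butter(2, 2 / (reference$fs / 2), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  iqr <- stats::IQR(x)
  if (iqr == 0) {
    rf_log("detect_reference_peaks: constant reference; no peaks", force = TRUE)
    return(peak_train(integer(0), reference$fs))
  }
  idx <- find_peaks(x,
                    min_distance = round(config$peak_min_distance_s * reference$fs),
                    min_prominence = config$peak_min_prominence * iqr)
  peak_train(idx - 1L, reference$fs)
}

#' Set of fixed-length multichannel windows
#'
#' `data` is an `n x channels x snippet_len` array; `meta` records each
#' window's subject, scenario and 0-based start index; `labels` (once
#' assigned) mark whether a breathing peak falls in the window's central
#' region.
#'
#' @param data Numeric array `n x C x L`.
#' @param meta Data frame with columns `subject_id`, `scenario`, `start`.
#' @param channels Character vector of channel names (length `C`).
#' @param fs Sampling rate of the underlying timeline.
#' @param labels Optional binary vector of length `n`.
#' @return An object of class `snippet_set`.
#' @export
snippet_set <- function(data, meta, channels, fs, labels = NULL) {
  stopifnot(length(dim(data)) == 3L)
  n <- dim(data)[1]
  if (nrow(meta) != n) stop("snippet_set: meta rows != window count")
  if (dim(data)[2] != length(channels)) {
    stop("snippet_set: channel names do not match data")
  }
  if (!is.null(labels)) {
    if (length(labels) != n || !all(labels %in% c(0, 1))) {
      stop("snippet_set: labels must be binary, one per window")
    }
    labels <- as.integer(labels)
  }
  structure(list(data = data, meta = meta, channels = channels,
                 fs = fs, labels = labels),
            class = "snippet_set")
}

#' @export
print.snippet_set <- function(x, ...) {
  cat(sprintf("<snippet_set: %d windows x %d channels x %d samples%s>\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              if (is.null(x$labels)) "" else
                sprintf("; %d positive", sum(x$labels))))
  invisible(x)
}

#' Cut aligned channels into overlapping snippets
#'
#' Windows of `snippet_len` samples start at 0, `step`, `2*step`, ... with
#' `step = snippet_len - overlap`; the window count is
#' `floor((N - snippet_len) / step) + 1`. Training uses overlap 190
#' (step 11) and testing overlap 200 (step 1).
#'
#' @param traces Named list of aligned [channel_trace] objects (equal
#'   length and rate). The list order fixes the channel order of the set.
#' @param snippet_len Window length in samples.
#' @param overlap Overlap between consecutive windows, `0 <= overlap <
#'   snippet_len`.
#' @param subject_id,scenario Provenance recorded per window.
#' @return An unlabeled [snippet_set].
#' @export
make_snippets <- function(traces, snippet_len = 201L, overlap,
                          subject_id = "unknown", scenario = "city") {
  stopifnot(is.list(traces), length(traces) >= 1L)
  lens <- vapply(traces, length, integer(1))
  fss <- vapply(traces, function(t) t$fs, numeric(1))
  if (length(unique(lens)) != 1L) stop("make_snippets: traces differ in length")
  if (length(unique(fss)) != 1L) stop("make_snippets: traces differ in rate")
  N <- lens[1]
  snippet_len <- as.integer(snippet_len); overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= snippet_len) {
    stop("make_snippets: need 0 <= overlap < snippet_len")
  }
  if (N < snippet_len) {
    stop("make_snippets: traces shorter (", N, ") than snippet_len (",
         snippet_len, ")")
  }
  step <- snippet_len - overlap
  starts0 <- seq.int(0L, N - snippet_len, by = step) # 0-based
  n <- length(starts0)
  C <- length(traces)
  data <- array(0, c(n, C, snippet_len))
  idx <- outer(starts0 + 1L, seq_len(snippet_len) - 1L, `+`)
  for (c in seq_len(C)) {
    data[, c, ] <- traces[[c]]$samples[idx]
  }
  meta <- data.frame(subject_id = rep(subject_id, n),
                     scenario = rep(scenario, n),
                     start = starts0, stringsAsFactors = FALSE)
  nm <- names(traces) %||% vapply(traces, function(t) t$name, character(1))
  snippet_set(data, meta, nm, fss[1])
}

#' Label snippets by central breathing events
#'
#' A window is labelled 1 iff some reference peak lies within
#' `tolerance` samples of the window center
#' `start + (snippet_len - 1)/2`, i.e. the breathing event sits in the
#' central region of the snippet; otherwise 0.
#'
#' @param set An unlabeled (or to-be-relabelled) [snippet_set].
#' @param peaks A [peak_train] on the same timeline.
#' @param tolerance Half-width of the central region in samples.
#' @return The set with binary `labels` filled in.
#' @export
label_snippets <- function(set, peaks, tolerance = 50L) {
  stopifnot(inherits(set, "snippet_set"), inherits(peaks, "peak_train"))
  L <- dim(set$data)[3]
  centers <- set$meta$start + (L - 1) / 2
  p <- peaks$indices
  if (!length(p)) {
    set$labels <- integer(dim(set$data)[1])
    return(set)
  }
  n_upto_hi <- findInterval(centers + tolerance, p)
  n_below_lo <- findInterval(centers - tolerance - 0.5, p)
  set$labels <- as.integer(n_upto_hi > n_below_lo)
  set
}

#' Concatenate snippet sets with identical geometry
#' @param sets List of [snippet_set] objects with equal channels, length
#'   and rate.
#' @return One combined [snippet_set].
#' @export
combine_snippet_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  if (length(sets) == 1L) return(sets[[1]])
  ch <- sets[[1]]$channels; L <- dim(sets[[1]]$data)[3]
  for (s in sets) {
    if (!identical(s$channels, ch) || dim(s$data)[3] != L) {
      stop("combine_snippet_sets: incompatible sets")
    }
  }
  ns <- vapply(sets, function(s) dim(s$data)[1], integer(1))
  data <- array(0, c(sum(ns), length(ch), L))
  off <- 0L
  for (s in sets) {
    data[(off + 1L):(off + dim(s$data)[1]), , ] <- s$data
    off <- off + dim(s$data)[1]
  }
  labels <- if (all(!vapply(sets, function(s) is.null(s$labels), logical(1)))) {
    unlist(lapply(sets, function(s) s$labels))
  }
  snippet_set(data, do.call(rbind, lapply(sets, function(s) s$meta)),
              ch, sets[[1]]$fs, labels)
}

# preprocessed recording -> labeled snippet set at the given overlap
recording_to_snippets <- function(rec, overlap, config = pipeline_config(),
                                  channels = c("piezo", "acc", "video_belt",
                                               "video_chest")) {
  missing <- setdiff(c(channels, "reference"), names(rec$channels))
  if (length(missing)) {
    stop("recording_to_snippets: recording lacks channel(s): ",
         paste(missing, collapse = ", "), " (run preprocess_recording first)")
  }
  set <- make_snippets(rec$channels[channels], config$snippet_len, overlap,
                       subject_id = rec$subject_id, scenario = rec$scenario)
  peaks <- detect_reference_peaks(rec$channels$reference, config)
  label_snippets(set, peaks, config$label_tolerance)
}

#' Leave-one-subject-out split
#'
#' Builds the training set (all snippets of the other subjects, overlap
#' `train_overlap`) and the test set (all snippets of the held-out
#' subject, overlap `test_overlap`) from preprocessed recordings. Subject
#' sets are disjoint by construction.
#'
#' @param recordings List of preprocessed [multimodal_recording] objects
#'   (see [preprocess_recording]); several scenarios per subject are
#'   pooled.
#' @param held_out_subject Subject id to test on; must be present.
#' @param config A [pipeline_config].
#' @return List with labeled `train` and `test` [snippet_set]s.
#' @export
split_loso <- function(recordings, held_out_subject,
                       config = pipeline_config()) {
  subjects <- vapply(recordings, function(r) r$subject_id, character(1))
  if (length(unique(subjects)) < 2L) stop("split_loso: need >= 2 subjects")
  if (!held_out_subject %in% subjects) {
    stop("split_loso: unknown subject '", held_out_subject, "'")
  }
  test_recs <- recordings[subjects == held_out_subject]
  train_recs <- recordings[subjects != held_out_subject]
  list(
    train = combine_snippet_sets(
      lapply(train_recs, recording_to_snippets,
             overlap = config$train_overlap, config = config)),
    test = combine_snippet_sets(
      lapply(test_recs, recording_to_snippets,
             overlap = config$test_overlap, config = config)))
}

#' Respiratory rate from predicted snippet labels
#'
#' Utility on top of the classifier output (not part of the evaluation
#' protocol, which scores snippet classification itself): consecutive
#' positive test windows (step 1) are merged into events at their run
#' centers, and the rate is the event count scaled to breaths per minute.
#'
#' @param pred Binary predictions over consecutive step-1 windows.
#' @param fs Timeline sampling rate in Hz.
#' @param step Window step in samples.
#' @return Estimated rate in breaths per minute.
#' @export
estimate_rate_bpm <- function(pred, fs, step = 1L) {
  r <- rle(as.integer(pred))
  n_events <- sum(r$values == 1L)
  duration_min <- length(pred) * step / fs / 60
  if (duration_min == 0) return(0)
  n_events / duration_min
}
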