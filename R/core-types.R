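#' Single-channel trace
#'
#' A named, uniformly sampled real-valued signal. This is the atomic unit
#' every processing step consumes and produces. Sample values are in
#' arbitrary units (au); time of sample `i` (0-based) is `i / fs` seconds.
#'
#' @param name Channel identifier, e.g. `"piezo"`, `"acc1_x"`, `"video_belt"`,
#'   `"reference"`, or a derived name such as `"acc"` for the denoised
#'   accelerometer combination.
#' @param samples Numeric vector of finite sample values, length >= 1.
#' @param fs Sampling rate in Hz, > 0.
#' @return An object of class `channel_trace` with fields `name`, `samples`,
#'   `fs`.
#' @examples
#' tr <- channel_trace("piezo", sin(2 * pi * 0.25 * seq(0, 10, by = 0.01)), 100)
#' duration_s(tr)
#' @export
channel_trace <- function(name, samples, fs) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("channel_trace '", name, "': needs at least one sample")
  }
  if (!all(is.finite(samples))) {
    stop("channel_trace '", name, "': samples must be finite (no NA/NaN/Inf)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("channel_trace '", name, "': fs must be a single positive number")
  }
  structure(list(name = name, samples = samples, fs = as.numeric(fs)),
            class = "channel_trace")
}

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf("<channel_trace '%s': %d samples @ %g Hz (%.2f s)>\n",
              x$name, length(x$samples), x$fs, duration_s(x)))
  invisible(x)
}

#' @export
length.channel_trace <- function(x) length(x$samples)

#' Duration of a trace in seconds
#' @param trace A `channel_trace`.
#' @return Duration `length(samples) / fs` in seconds.
#' @export
duration_s <- function(trace) length(trace$samples) / trace$fs

#' Replace the samples of a trace, keeping name and rate
#' @keywords internal
#' @noRd
trace_with <- function(trace, samples, fs = trace$fs, name = trace$name) {
  channel_trace(name, samples, fs)
}

#' Driving scenarios recognised by the data model
#' @export
SCENARIOS <- c("city", "highway", "countryside")

#' Multimodal recording
#'
#' A set of synchronized channels for one subject in one driving scenario.
#' Channels may have different sampling rates (e.g. 100 Hz hub channels and
#' 10 fps video), but must cover the same duration to within one sample
#' period of the slowest channel.
#'
#' @param subject_id Opaque subject identifier string.
#' @param scenario One of `"city"`, `"highway"`, `"countryside"`.
#' @param channels Named list of [channel_trace] objects; names must equal
#'   each trace's own `name`.
#' @return An object of class `multimodal_recording`.
#' @export
multimodal_recording <- function(subject_id, scenario, channels) {
  subject_id <- as.character(subject_id)
  stopifnot(length(subject_id) == 1L, nzchar(subject_id))
  scenario <- match.arg(scenario, SCENARIOS)
  if (!is.list(channels) || length(channels) < 1L) {
    stop("multimodal_recording: need at least one channel")
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("multimodal_recording: channels must be a named list")
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!inherits(ch, "channel_trace")) {
      stop("multimodal_recording: channel '", nm, "' is not a channel_trace")
    }
    if (!identical(ch$name, nm)) {
      stop("multimodal_recording: channel list name '", nm,
           "' does not match trace name '", ch$name, "'")
    }
  }
  durs <- vapply(channels, duration_s, numeric(1))
  slowest_period <- 1 / min(vapply(channels, function(ch) ch$fs, numeric(1)))
  if (max(durs) - min(durs) > slowest_period + 1e-9) {
    stop(sprintf(
      "multimodal_recording: channel durations disagree by %.4f s (> one period of the slowest channel, %.4f s)",
      max(durs) - min(durs), slowest_period))
  }
  structure(list(subject_id = subject_id, scenario = scenario,
                 channels = channels, duration_s = max(durs)),
            class = "multimodal_recording")
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat(sprintf("<multimodal_recording subject=%s scenario=%s (%.1f s)>\n",
              x$subject_id, x$scenario, x$duration_s))
  for (ch in x$channels) {
    cat(sprintf("  %-12s %7d samples @ %6g Hz\n",
                ch$name, length(ch$samples), ch$fs))
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the pipeline with validated defaults:
#' the respiration band for accelerometer filtering, the unified sampling
#' rate (200 Hz), snippet geometry (201 samples; train/test overlaps 190 and
#' 200), the event-labelling tolerance, reference peak-detection settings,
#' and the fusion-model hyperparameters (4 filters of length 20, dropout
#' 0.5, max-pooling of size 4, Adam with learning rate 1e-3).
#'
#' @param bandpass_low_hz,bandpass_high_hz Respiration band edges in Hz.
#' @param bandpass_order Butterworth order (applied forward and backward,
#'   so the effective order is twice this).
#' @param median_kernel Odd median-filter kernel length in samples.
#' @param target_fs Unified sampling rate in Hz.
#' @param snippet_len Window length in samples.
#' @param train_overlap,test_overlap Window overlaps in samples.
#' @param label_tolerance Half-width in samples of the central region a
#'   breathing peak must fall into for a snippet to be labelled 1.
#' @param peak_min_distance_s Minimum spacing between reference peaks in
#'   seconds (1.5 s caps the detectable rate at 40 breaths/min).
#' @param peak_min_prominence Minimum peak prominence as a fraction of the
#'   trace interquartile range.
#' @param suppress_window_s Segment length in seconds for the windowed
#'   (Hann, half-overlap) spectral suppression used on full recordings;
#'   `0` forces the single full-record transform.
#' @param n_filters,filter_len Convolution bank: number of filters and
#'   filter length in samples.
#' @param dropout Dropout rate applied to the convolution feature map
#'   during training.
#' @param pool_size Max-pooling width (stride equals width).
#' @param epochs,batch_size,learning_rate Training-loop settings (Adam).
#' @param class_weighting Logical; weight the two classes inversely to
#'   their frequency in the training labels.
#' @param threshold Score threshold for binarizing the sigmoid output.
#' @param seed Integer seed governing weight initialization, shuffling and
#'   dropout.
#' @param delimiter Field delimiter for text I/O, or `"auto"` to detect.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(bandpass_low_hz = 0.1,
                            bandpass_high_hz = 0.7,
                            bandpass_order = 2L,
                            median_kernel = 5L,
                            target_fs = 200,
                            snippet_len = 201L,
                            train_overlap = 190L,
                            test_overlap = 200L,
                            label_tolerance = 50L,
                            peak_min_distance_s = 1.5,
                            peak_min_prominence = 0.1,
                            suppress_window_s = 20,
                            n_filters = 4L,
                            filter_len = 20L,
                            dropout = 0.5,
                            pool_size = 4L,
                            epochs = 20L,
                            batch_size = 64L,
                            learning_rate = 1e-3,
                            class_weighting = TRUE,
                            threshold = 0.5,
                            seed = 1L,
                            delimiter = "auto") {
  cfg <- list(
    bandpass_low_hz = bandpass_low_hz, bandpass_high_hz = bandpass_high_hz,
    bandpass_order = as.integer(bandpass_order),
    median_kernel = as.integer(median_kernel), target_fs = target_fs,
    snippet_len = as.integer(snippet_len),
    train_overlap = as.integer(train_overlap),
    test_overlap = as.integer(test_overlap),
    label_tolerance = as.integer(label_tolerance),
    peak_min_distance_s = peak_min_distance_s,
    peak_min_prominence = peak_min_prominence,
    suppress_window_s = suppress_window_s,
    n_filters = as.integer(n_filters), filter_len = as.integer(filter_len),
    dropout = dropout, pool_size = as.integer(pool_size),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, class_weighting = isTRUE(class_weighting),
    threshold = threshold, seed = as.integer(seed), delimiter = delimiter)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!(bandpass_low_hz > 0 && bandpass_low_hz < bandpass_high_hz &&
          bandpass_high_hz < target_fs / 2)) {
      stop("pipeline_config: need 0 < bandpass_low < bandpass_high < target_fs/2")
    }
    if (median_kernel < 1L || median_kernel %% 2L == 0L) {
      stop("pipeline_config: median_kernel must be odd and >= 1")
    }
    if (!(snippet_len > train_overlap && snippet_len > test_overlap &&
          train_overlap >= 0L && test_overlap >= 0L)) {
      stop("pipeline_config: need snippet_len > overlaps >= 0")
    }
    if (dropout < 0 || dropout >= 1) stop("pipeline_config: dropout in [0, 1)")
    if (label_tolerance < 0L) stop("pipeline_config: label_tolerance >= 0")
    if (n_filters < 1L || filter_len < 1L || pool_size < 1L) {
      stop("pipeline_config: model sizes must be positive")
    }
  })
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys raise an error (a misspelt parameter should not be silently
#' ignored); missing keys take their defaults.
#'
#' @param path Path to a YAML file whose keys are [pipeline_config]
#'   argument names.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), c(known, "channel_map"))
  if (length(extra)) {
    stop("read_config: unknown configuration keys: ",
         paste(extra, collapse = ", "))
  }
  cfg <- do.call(pipeline_config, vals[intersect(names(vals), known)])
  if (!is.null(vals$channel_map)) attr(cfg, "channel_map") <- vals$channel_map
  cfg
}

#' Conditional logging to stderr
#'
#' Verbosity is controlled with `options(respfusion.verbose = TRUE/FALSE)`;
#' warnings from degenerate inputs are always emitted through this channel.
#' @keywords internal
#' @noRd
rf_log <- function(..., force = FALSE) {
  if (force || isTRUE(getOption("respfusion.verbose", FALSE))) {
    message("[respfusion] ", ...)
  }
  invisible(NULL)
}
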