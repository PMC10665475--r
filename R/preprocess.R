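#' Piezoelectric channel passthrough
#'
#' The seat-belt pressure transducer converts chest expansion directly into
#' voltage, so its trace enters the fusion stage untouched.
#'
#' @param trace A [channel_trace].
#' @return The identical trace.
#' @export
piezo_passthrough <- function(trace) {
  stopifnot(inherits(trace, "channel_trace"))
  trace
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt]), so the pass band is traversed with zero phase lag
#' and breathing-peak positions are not shifted. The default band
#' 0.1-0.7 Hz covers 6-42 breaths/min.
#'
#' @param trace A [channel_trace].
#' @param low_hz,high_hz Band edges, `0 < low < high < fs/2`.
#' @param order Butterworth order of the underlying filter (effective
#'   attenuation is doubled by the two passes).
#' @return Filtered trace, same length and rate.
#' @export
bandpass <- function(trace, low_hz, high_hz, order = 2L) {
  stopifnot(inherits(trace, "channel_trace"))
  fs <- trace$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("bandpass: need 0 < low_hz < high_hz < fs/2 (fs = ", fs, ")")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  # odd-reflection padding keeps the start/end transients of the forward
  # and backward passes out of the record (the low band edge has a long
  # impulse response, so unpadded edges would leak across the spectrum)
  x <- trace$samples
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * fs / low_hz))
  if (pad > 0L) {
    head_ref <- 2 * x[1] - x[(pad + 1L):2L]
    tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(head_ref, x, tail_ref))
    y <- y[(pad + 1L):(pad + n)]
  } else {
    y <- signal::filtfilt(bf, x)
  }
  trace_with(trace, y)
}

#' Combine three accelerometer axes by principal component analysis
#'
#' Projects the mean-centered (x, y, z) sample cloud onto its first
#' principal component, collapsing the three axes into the single trace
#' that carries most of the motion variance. The sign of the component is
#' fixed deterministically: it is flipped, if necessary, so that its
#' loading on the axis of largest variance is positive.
#'
#' @param acc_x,acc_y,acc_z Equal-length, equal-rate [channel_trace]
#'   objects for the three axes.
#' @param name Name for the combined output trace.
#' @return A [channel_trace] of PC1 scores (unit-norm loading vector), with
#'   the explained-variance share of PC1 attached as attribute
#'   `"explained"`.
#' @export
pca_axis_combine <- function(acc_x, acc_y, acc_z, name = "acc_pc1") {
  for (tr in list(acc_x, acc_y, acc_z)) stopifnot(inherits(tr, "channel_trace"))
  if (length(acc_x) != length(acc_y) || length(acc_y) != length(acc_z)) {
    stop("pca_axis_combine: axis traces differ in length")
  }
  if (acc_x$fs != acc_y$fs || acc_y$fs != acc_z$fs) {
    stop("pca_axis_combine: axis traces differ in sampling rate")
  }
  M <- cbind(acc_x$samples, acc_y$samples, acc_z$samples)
  M <- sweep(M, 2L, colMeans(M))
  C <- crossprod(M) / max(1L, nrow(M) - 1L)
  if (all(abs(C) < 1e-24)) {
    rf_log("pca_axis_combine: constant axes (rank-0 covariance); returning zeros",
           force = TRUE)
    out <- trace_with(acc_x, numeric(nrow(M)), name = name)
    attr(out, "explained") <- NA_real_
    return(out)
  }
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  dominant_axis <- which.max(diag(C))
  if (v[dominant_axis] < 0) v <- -v
  out <- trace_with(acc_x, drop(M %*% v), name = name)
  attr(out, "explained") <- eg$values[1L] / sum(eg$values)
  out
}

#' Per-bin spectral suppression factor
#'
#' For each frequency bin `k`, the factor
#' `SF(k) = exp(-|X2(k)| / mu(|X1|))` attenuates the signal channel in
#' proportion to how strongly the noise-only reference channel expresses
#' that bin, on the scale of the signal channel's mean spectral magnitude
#' `mu(|X1|)`. A bin silent in the reference passes unchanged (SF = 1); a
#' bin as loud as the signal's average is damped to `exp(-1)`.
#'
#' @param abs_X1 Magnitudes `|X1(k)|` of the signal-plus-noise channel.
#' @param abs_X2 Magnitudes `|X2(k)|` of the noise-only channel, same
#'   length.
#' @return Numeric vector of suppression factors in (0, 1].
#' @export
suppression_factor <- function(abs_X1, abs_X2) {
  if (length(abs_X1) != length(abs_X2)) {
    stop("suppression_factor: spectra differ in length")
  }
  if (any(abs_X1 < 0) || any(abs_X2 < 0)) {
    stop("suppression_factor: magnitudes must be non-negative")
  }
  mu <- mean(abs_X1)
  if (mu == 0) stop("suppression_factor: degenerate signal (all-zero X1)")
  exp(-abs_X2 / mu)
}

#' Reference-channel spectral suppression
#'
#' Denoises a signal channel `x1` (respiration + vehicle noise) using a
#' co-located noise-only channel `x2`: both are taken to the frequency
#' domain in a single transform, each bin of `X1` is scaled by the real
#' factor [suppression_factor] derived from `|X2|`, and the suppressed
#' spectrum is inverse-transformed. Because the factor depends only on
#' magnitudes it is conjugate-symmetric for real inputs, so the inverse
#' transform is real up to numerical round-off; the residual imaginary
#' part is checked against `tol` and discarded.
#'
#' @param x1 Signal-plus-noise [channel_trace].
#' @param x2 Noise-only [channel_trace]; equal length and rate.
#' @param window,hop Optional windowed variant for long signals:
#'   Hann-tapered segments of `window` samples advanced by `hop`
#'   (default `window/2`) are transformed, suppressed and overlap-added
#'   (the taper sums to a constant at half-window hop, and the residual
#'   envelope is divided out). The taper matters: with one untapered
#'   full-length transform, spectral leakage from strong narrowband
#'   components forms a pedestal many times `mu(|X1|)`, and the
#'   exponential factor then annihilates the whole pass band. The
#'   single-transform form remains the default for short records.
#' @param tol Bound on the admissible imaginary residue, relative to the
#'   output scale.
#' @return A list of class `spectral_suppression` with elements `X1`, `X2`
#'   (complex spectra), `SF`, `X_supp`, and `denoised` (a [channel_trace]).
#'   For the windowed variant the spectra are those of the first window.
#' @export
spectral_suppress <- function(x1, x2, window = NULL, hop = NULL, tol = 1e-9) {
  stopifnot(inherits(x1, "channel_trace"), inherits(x2, "channel_trace"))
  if (length(x1) != length(x2)) stop("spectral_suppress: unequal lengths")
  if (x1$fs != x2$fs) stop("spectral_suppress: unequal sampling rates")
  if (is.null(window)) {
    res <- suppress_block(x1$samples, x2$samples, tol)
    out <- list(X1 = res$X1, X2 = res$X2, SF = res$SF, X_supp = res$X_supp,
                denoised = trace_with(x1, res$y, name = paste0(x1$name, "_denoised")))
  } else {
    n <- length(x1)
    window <- as.integer(min(window, n))
    hop <- as.integer(hop %||% max(1L, window %/% 2L))
    stopifnot(window >= 2L, hop >= 1L, hop <= window)
    taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window) - 1L) / (window - 1L))
    # reflect-pad both channels so every retained sample gets full taper
    # coverage (otherwise the near-zero taper weights at the record edges
    # would be divided out and amplify round-off there)
    ps <- min(n - 1L, window)
    pad_ends <- function(x) c(x[(ps + 1L):2L], x, x[(n - 1L):(n - ps)])
    s1 <- pad_ends(x1$samples)
    s2 <- pad_ends(x2$samples)
    np <- length(s1)
    y <- numeric(np)
    wsum <- numeric(np)
    starts <- seq(1L, max(1L, np - window + 1L), by = hop)
    if (starts[length(starts)] + window - 1L < np) {
      starts <- c(starts, np - window + 1L)
    }
    first <- NULL
    for (s in starts) {
      idx <- s:(s + window - 1L)
      res <- suppress_block(s1[idx] * taper, s2[idx] * taper, tol)
      if (is.null(first)) first <- res
      y[idx] <- y[idx] + res$y
      wsum[idx] <- wsum[idx] + taper
    }
    y <- (y / pmax(wsum, 1e-6))[(ps + 1L):(ps + n)]
    out <- list(X1 = first$X1, X2 = first$X2, SF = first$SF,
                X_supp = first$X_supp,
                denoised = trace_with(x1, y, name = paste0(x1$name, "_denoised")))
  }
  class(out) <- "spectral_suppression"
  out
}

suppress_block <- function(s1, s2, tol) {
  X1 <- stats::fft(s1)
  X2 <- stats::fft(s2)
  SF <- suppression_factor(Mod(X1), Mod(X2))
  X_supp <- SF * X1
  y_c <- stats::fft(X_supp, inverse = TRUE) / length(X_supp)
  scale <- max(abs(Re(y_c)), 1e-300)
  if (max(abs(Im(y_c))) > tol * max(scale, 1)) {
    stop("spectral_suppress: imaginary residue exceeds tolerance")
  }
  list(X1 = X1, X2 = X2, SF = SF, X_supp = X_supp, y = Re(y_c))
}

#' Full accelerometer denoising pipeline
#'
#' The seat-belt sensor (respiration + vehicle noise) and the seat sensor
#' (vehicle noise only) are each band-pass filtered to the respiration
#' band and collapsed to one trace by [pca_axis_combine]; the seat trace
#' then drives [spectral_suppress] of the belt trace.
#'
#' @param acc1_xyz,acc2_xyz Lists of three [channel_trace] axes (x, y, z)
#'   for the seat-belt and seat accelerometers; equal sampling rates.
#' @param config A [pipeline_config] providing the band edges and filter
#'   order.
#' @param combine `"pca"` (default) collapses axes to the first principal
#'   component; `"norm"` uses the Euclidean 3-axis magnitude instead.
#' @return Denoised [channel_trace] named `"acc"`.
#' @export
denoise_accelerometer <- function(acc1_xyz, acc2_xyz,
                                  config = pipeline_config(),
                                  combine = c("pca", "norm")) {
  combine <- match.arg(combine)
  stopifnot(length(acc1_xyz) == 3L, length(acc2_xyz) == 3L)
  fs <- unique(vapply(c(acc1_xyz, acc2_xyz), function(t) t$fs, numeric(1)))
  if (length(fs) != 1L) stop("denoise_accelerometer: sensors differ in sampling rate")
  one_sensor <- function(axes, nm) {
    filt <- lapply(axes, bandpass, low_hz = config$bandpass_low_hz,
                   high_hz = config$bandpass_high_hz,
                   order = config$bandpass_order)
    if (combine == "pca") {
      pca_axis_combine(filt[[1]], filt[[2]], filt[[3]], name = nm)
    } else {
      trace_with(filt[[1]], sqrt(filt[[1]]$samples^2 + filt[[2]]$samples^2 +
                                   filt[[3]]$samples^2), name = nm)
    }
  }
  a1 <- one_sensor(acc1_xyz, "acc1_combined")
  a2 <- one_sensor(acc2_xyz, "acc2_combined")
  win <- round((config$suppress_window_s %||% 0) * fs)
  if (win > 0 && length(a1) > win) {
    out <- spectral_suppress(a1, a2, window = win)$denoised
  } else {
    out <- spectral_suppress(a1, a2)$denoised
  }
  out$name <- "acc"
  out
}

#' Resample a trace to a target rate
#'
#' Rational-ratio polyphase resampling ([signal::resample]); the pipeline
#' uses it to bring every channel to the unified 200 Hz rate. Upsampling
#' is the intended direction; downsampling is allowed (the FIR
#' interpolation filter anti-aliases) and logged.
#'
#' @param trace A [channel_trace].
#' @param target_fs Target rate in Hz.
#' @return Trace at `target_fs` with length scaled by `target_fs/fs`.
#' @export
resample_to <- function(trace, target_fs = 200) {
  stopifnot(inherits(trace, "channel_trace"))
  if (!is.numeric(target_fs) || target_fs <= 0) {
    stop("resample_to: target_fs must be positive")
  }
  if (target_fs == trace$fs) return(trace)
  if (target_fs < trace$fs) {
    rf_log("resample_to: downsampling ", trace$name, " from ", trace$fs,
           " to ", target_fs, " Hz", force = TRUE)
  }
  fr <- ratio_pq(target_fs / trace$fs)
  y <- signal::resample(trace$samples, fr[1], fr[2])
  n_out <- round(length(trace$samples) * target_fs / trace$fs)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  trace_with(trace, y, fs = target_fs)
}

# smallest integer ratio p/q equal to x (within tolerance)
ratio_pq <- function(x, max_den = 1000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("resample_to: rate ratio ", x, " has no small rational form")
}

#' Sliding median filter
#'
#' Running median with reflected edges; removes single-sample spikes
#' without flattening breath-scale structure.
#'
#' @param trace A [channel_trace].
#' @param kernel Odd window length in samples; `1` is the identity.
#' @return Filtered trace, same length.
#' @export
median_filter <- function(trace, kernel = 5L) {
  stopifnot(inherits(trace, "channel_trace"))
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L) stop("median_filter: kernel must be odd, >= 1")
  if (kernel == 1L) return(trace)
  x <- trace$samples
  n <- length(x)
  h <- kernel %/% 2L
  if (n == 1L) return(trace)
  pad <- min(h, n - 1L)
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  if (pad < h) { # very short trace: extend reflection by repetition
    xp <- c(rep(xp[1L], h - pad), xp, rep(xp[length(xp)], h - pad))
  }
  y <- stats::runmed(xp, kernel, endrule = "keep")
  trace_with(trace, y[(h + 1L):(h + n)])
}

#' Normalize amplitude to [-1, 1]
#'
#' Affine map of the observed `[min, max]` onto `[-1, 1]`, applied per
#' recording so relative amplitude across snippets is preserved. A
#' constant trace has no amplitude to normalize and maps to all zeros with
#' a logged warning.
#'
#' @param trace A [channel_trace].
#' @return Normalized trace.
#' @export
normalize_amplitude <- function(trace) {
  stopifnot(inherits(trace, "channel_trace"))
  x <- trace$samples
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    rf_log("normalize_amplitude: constant trace '", trace$name,
           "' mapped to zeros", force = TRUE)
    return(trace_with(trace, numeric(length(x))))
  }
  trace_with(trace, 2 * (x - lo) / (hi - lo) - 1)
}

#' Condition a raw recording for the fusion stage
#'
#' Applies the per-sensor stage (piezo passthrough; accelerometer pair
#' denoised via band-pass, PCA and reference-channel spectral
#' suppression; video traces taken as-is), then the unified stage
#' (resample everything to `target_fs`, median filter, amplitude
#' normalization to `[-1, 1]`). The chest-belt reference is resampled but
#' neither filtered nor normalized, since it only feeds peak detection.
#'
#' @param rec A [multimodal_recording] with channels `piezo`,
#'   `acc1_x/y/z`, `acc2_x/y/z`, `video_belt`, `video_chest`,
#'   `reference`.
#' @param config A [pipeline_config].
#' @return A [multimodal_recording] with channels
#'   `piezo, acc, video_belt, video_chest, reference`, all at
#'   `config$target_fs`.
#' @export
preprocess_recording <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "multimodal_recording"))
  need <- c("piezo", paste0("acc1_", c("x", "y", "z")),
            paste0("acc2_", c("x", "y", "z")),
            "video_belt", "video_chest", "reference")
  missing <- setdiff(need, names(rec$channels))
  if (length(missing)) {
    stop("preprocess_recording: missing channel(s): ",
         paste(missing, collapse = ", "))
  }
  ch <- rec$channels
  acc <- denoise_accelerometer(ch[c("acc1_x", "acc1_y", "acc1_z")],
                               ch[c("acc2_x", "acc2_y", "acc2_z")], config)
  unified <- function(tr, normalize = TRUE) {
    tr <- resample_to(tr, config$target_fs)
    tr <- median_filter(tr, config$median_kernel)
    if (normalize) tr <- normalize_amplitude(tr)
    tr
  }
  out <- list(
    piezo = unified(piezo_passthrough(ch$piezo)),
    acc = unified(acc),
    video_belt = unified(ch$video_belt),
    video_chest = unified(ch$video_chest),
    reference = unified(ch$reference, normalize = FALSE))
  out <- Map(function(tr, nm) { tr$name <- nm; tr }, out, names(out))
  # resampling different native rates can leave off-by-one lengths; trim
  n <- min(vapply(out, length, integer(1)))
  out <- lapply(out, function(tr) trace_with(tr, tr$samples[seq_len(n)]))
  multimodal_recording(rec$subject_id, rec$scenario, out)
}
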