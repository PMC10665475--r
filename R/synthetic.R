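#' Scenario noise profile for the simulator
#'
#' The three driving scenarios differ only through these parameters:
#' the band and gain of the shared vehicle noise, the rate of transient
#' events (bumps, stops) and the slow illumination drift seen by the
#' video channels. The named defaults order the scenarios by road
#' roughness (highway < city < countryside); the numbers are simulator
#' choices, not measured values.
#'
#' @param name Scenario name.
#' @param noise_band_hz Two-element band of the shared vehicle noise in
#'   Hz. The noise is resonance-dominated — body sway (0.35-0.6 Hz,
#'   inside the respiration band), suspension (1.2-2.5 Hz) and
#'   engine/road order (8-15 Hz) — over a weak flat broadband floor;
#'   road vibration concentrates at such structural resonances, and that
#'   concentration is what the reference-channel suppression exploits.
#' @param noise_gain Overall scale of the shared noise (respiration
#'   amplitude is of order 1).
#' @param transient_rate_per_min Expected transients per minute.
#' @param drift_gain Amplitude of the slow drift added to video traces.
#' @return An object of class `sim_scenario_profile`.
#' @export
sim_scenario_profile <- function(name, noise_band_hz = c(0.1, 20),
                                 noise_gain = 1, transient_rate_per_min = 3,
                                 drift_gain = 0.3) {
  stopifnot(noise_gain >= 0, transient_rate_per_min >= 0, drift_gain >= 0,
            length(noise_band_hz) == 2L, noise_band_hz[1] < noise_band_hz[2])
  structure(list(name = name, noise_band_hz = noise_band_hz,
                 noise_gain = noise_gain,
                 transient_rate_per_min = transient_rate_per_min,
                 drift_gain = drift_gain),
            class = "sim_scenario_profile")
}

#' @rdname sim_scenario_profile
#' @export
default_profiles <- function() {
  list(
    city = sim_scenario_profile("city", noise_gain = 1.0,
                                transient_rate_per_min = 4, drift_gain = 0.3),
    highway = sim_scenario_profile("highway", noise_gain = 0.7,
                                   transient_rate_per_min = 1,
                                   drift_gain = 0.2),
    countryside = sim_scenario_profile("countryside", noise_gain = 1.3,
                                       transient_rate_per_min = 6,
                                       drift_gain = 0.4))
}

#' Simulated subject
#'
#' Fixes one virtual occupant's breathing dynamics and per-channel
#' coupling; the seed fixes every random draw made for this subject.
#'
#' @param subject_id Identifier string.
#' @param breathing_rate_bpm Base rate in breaths per minute (6-40).
#' @param rate_wander Relative amplitude of the slow rate modulation.
#' @param acc_gain,piezo_gain,video_gain Respiration coupling per sensor
#'   family.
#' @param video_lag_s Video trace lag behind chest movement, seconds.
#' @param seed Integer seed.
#' @return An object of class `sim_subject`.
#' @export
sim_subject <- function(subject_id, breathing_rate_bpm = 15,
                        rate_wander = 0.05, acc_gain = 1, piezo_gain = 1,
                        video_gain = 0.8, video_lag_s = 0.2, seed = 1L) {
  if (breathing_rate_bpm < 6 || breathing_rate_bpm > 40) {
    stop("sim_subject: breathing_rate_bpm outside the physiological band 6-40")
  }
  structure(list(subject_id = as.character(subject_id),
                 breathing_rate_bpm = breathing_rate_bpm,
                 rate_wander = rate_wander, acc_gain = acc_gain,
                 piezo_gain = piezo_gain, video_gain = video_gain,
                 video_lag_s = video_lag_s, seed = as.integer(seed)),
            class = "sim_subject")
}

#' Simulate a clean respiration waveform with exact peaks
#'
#' Quasi-periodic chest movement: the instantaneous rate is the base
#' rate modulated by a slow sinusoidal wander, the waveform is the shape
#' `sin(theta) - 0.3 cos(2 theta)` (a breath with a sharpened inhalation
#' crest whose maximum sits exactly at phase pi/2), and the ground-truth
#' peak train marks every crossing of that phase — exact by
#' construction, not detected.
#'
#' @param subject A [sim_subject].
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return List with `trace` (clean [channel_trace] named
#'   `"respiration"`) and `peaks` (a [peak_train], 0-based indices).
#' @export
simulate_respiration <- function(subject, duration_s, fs) {
  stopifnot(inherits(subject, "sim_subject"), duration_s > 0, fs > 0)
  set.seed(subject$seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  phi0 <- stats::runif(1, 0, 2 * pi)
  wander_f <- 0.01
  rate_hz <- subject$breathing_rate_bpm / 60 *
    (1 + subject$rate_wander * sin(2 * pi * wander_f * t + phi0))
  theta <- cumsum(2 * pi * rate_hz / fs)
  x <- sin(theta) - 0.3 * cos(2 * theta)
  targets <- seq(pi / 2, theta[n], by = 2 * pi)
  idx <- findInterval(targets, theta) # last sample with theta <= target
  idx <- pmin(pmax(idx, 1L), n)
  # snap to whichever neighbour is closer in phase
  snap <- ifelse(idx < n &
                   abs(theta[pmin(idx + 1L, n)] - targets) <
                     abs(theta[idx] - targets),
                 idx + 1L, idx)
  snap <- unique(snap[targets >= theta[1]])
  list(trace = channel_trace("respiration", x, fs),
       peaks = peak_train(snap - 1L, fs))
}

# band-limited Gaussian noise, unit standard deviation; weight "flat"
# keeps the spectrum flat within the band, "pink" applies 1/f weighting
shaped_noise <- function(n, fs, band, weight = c("flat", "pink")) {
  weight <- match.arg(weight)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * fs / n
  f <- abs(freqs)
  mask <- numeric(n)
  sel <- f >= band[1] & f <= band[2]
  mask[sel] <- if (weight == "pink") 1 / sqrt(pmax(f[sel], band[1])) else 1
  y <- Re(stats::fft(W * mask, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s
}

# amplitude-modulated narrowband resonance (body roll, suspension,
# engine order): a sinusoid with random frequency and phase whose
# envelope wanders slowly
resonance <- function(n, fs, f_range, amplitude) {
  t <- (seq_len(n) - 1L) / fs
  f0 <- stats::runif(1, f_range[1], f_range[2])
  ph <- stats::runif(1, 0, 2 * pi)
  am <- 1 + 0.3 * sin(2 * pi * stats::runif(1, 0.01, 0.04) * t +
                        stats::runif(1, 0, 2 * pi))
  amplitude * am * sin(2 * pi * f0 * t + ph)
}

# shared vehicle noise: narrowband resonances (body sway inside the
# respiration band, suspension, engine/road order) over a weak broadband
# floor; road-roughness structure is what the reference-channel
# suppression exploits
vehicle_noise <- function(n, fs, profile) {
  lo <- max(profile$noise_band_hz[1], 0.01)
  hi <- profile$noise_band_hz[2]
  profile$noise_gain *
    (resonance(n, fs, c(max(lo, 0.35), min(hi, 0.6)), 0.9) +
       resonance(n, fs, c(max(lo, 1.2), min(hi, 2.5)), 1.0) +
       resonance(n, fs, c(max(lo, 8), min(hi, 15)), 0.8) +
       0.01 * shaped_noise(n, fs, c(lo, hi)))
}

# Poisson train of oscillatory transients (road bumps, stops). The
# Gaussian envelope keeps each burst's spectrum concentrated around its
# 2-5 Hz carrier (a suspension response), well above the respiration band.
transient_train <- function(n, fs, rate_per_min, amplitude) {
  y <- numeric(n)
  k <- stats::rpois(1, rate_per_min * n / fs / 60)
  if (k == 0) return(y)
  onsets <- sort(sample.int(n, k, replace = TRUE))
  burst_len <- round(1.6 * fs)
  tt <- (seq_len(burst_len) - 1L) / fs - 0.8
  for (o in onsets) {
    f0 <- stats::runif(1, 2, 5)
    a <- amplitude * stats::runif(1, 0.5, 1.5)
    burst <- a * exp(-(tt / 0.25)^2 / 2) * sin(2 * pi * f0 * tt)
    span <- o:min(n, o + burst_len - 1L)
    y[span] <- y[span] + burst[seq_along(span)]
  }
  y
}

slow_drift <- function(n, fs) {
  t <- (seq_len(n) - 1L) / fs
  f <- stats::runif(3, 0.005, 0.04)
  ph <- stats::runif(3, 0, 2 * pi)
  a <- stats::runif(3, 0.3, 1)
  rowSums(sapply(seq_len(3), function(i) a[i] * sin(2 * pi * f[i] * t + ph[i])))
}

lagged <- function(x, lag_samples) {
  n <- length(x)
  lag_samples <- as.integer(lag_samples)
  if (lag_samples <= 0L) return(x)
  c(rep(x[1], lag_samples), x[seq_len(n - lag_samples)])
}

#' Simulate one multimodal in-cabin recording
#'
#' Emulates the deposited channel layout with known ground truth: the
#' piezoelectric belt sees nearly clean respiration; the seat-belt
#' accelerometer (3 axes) mixes respiration with the shared vehicle
#' noise; the seat accelerometer (3 axes) sees the shared noise only,
#' plus independent sensor noise; the two video traces are lagged,
#' rescaled respiration with illumination drift; the chest-belt
#' reference is respiration with negligible noise. Hub channels are
#' produced at `fs_hub` and video at `fs_video` so the resampling path
#' of the pipeline is exercised; the ground-truth peak train is on the
#' unified `fs_master` timeline.
#'
#' @param subject A [sim_subject].
#' @param profile A [sim_scenario_profile].
#' @param duration_s Duration in seconds.
#' @param fs_master Unified timeline rate (Hz).
#' @param fs_hub Native rate of piezo/accelerometer/reference channels.
#' @param fs_video Native video frame rate.
#' @return List with `recording` (a [multimodal_recording]) and `peaks`
#'   (ground-truth [peak_train] at `fs_master`).
#' @export
simulate_recording <- function(subject, profile, duration_s,
                               fs_master = 200, fs_hub = 100,
                               fs_video = 10) {
  stopifnot(inherits(subject, "sim_subject"),
            inherits(profile, "sim_scenario_profile"))
  if (fs_master %% fs_hub != 0 || fs_master %% fs_video != 0) {
    stop("simulate_recording: fs_hub and fs_video must divide fs_master")
  }
  resp <- simulate_respiration(subject, duration_s, fs_master)
  n <- length(resp$trace)
  set.seed(subject$seed + 7919L * match(profile$name, SCENARIOS, nomatch = 99L))
  noise <- vehicle_noise(n, fs_master, profile) +
    profile$noise_gain *
      transient_train(n, fs_master, profile$transient_rate_per_min,
                      amplitude = 2)
  r <- resp$trace$samples
  down <- function(x, fs_to) x[seq(1L, n, by = fs_master / fs_to)]
  wn <- function(m, sd) stats::rnorm(m, sd = sd)

  rh <- down(r, fs_hub); nh <- down(noise, fs_hub); m <- length(rh)
  w_resp <- c(0.9, 0.5, 0.25) * subject$acc_gain
  w_n1 <- c(1.0, 0.8, 0.6)
  w_n2 <- c(0.9, 1.0, 0.7)
  acc1 <- lapply(1:3, function(a) w_resp[a] * rh + w_n1[a] * nh + wn(m, 0.02))
  acc2 <- lapply(1:3, function(a) w_n2[a] * nh + wn(m, 0.02))
  piezo <- subject$piezo_gain * rh + 0.08 * nh + wn(m, 0.05)
  reference <- rh + wn(m, 0.01)

  lag_m <- round(subject$video_lag_s * fs_master)
  r_lag <- lagged(r, lag_m)
  nv <- round(duration_s * fs_video)
  vb <- subject$video_gain * down(r_lag, fs_video) +
    profile$drift_gain * slow_drift(nv, fs_video) + wn(nv, 0.05)
  vc <- 0.9 * subject$video_gain * down(lagged(r, round(1.5 * lag_m)), fs_video) +
    profile$drift_gain * slow_drift(nv, fs_video) + wn(nv, 0.05)

  ch <- list(
    piezo = channel_trace("piezo", piezo, fs_hub),
    acc1_x = channel_trace("acc1_x", acc1[[1]], fs_hub),
    acc1_y = channel_trace("acc1_y", acc1[[2]], fs_hub),
    acc1_z = channel_trace("acc1_z", acc1[[3]], fs_hub),
    acc2_x = channel_trace("acc2_x", acc2[[1]], fs_hub),
    acc2_y = channel_trace("acc2_y", acc2[[2]], fs_hub),
    acc2_z = channel_trace("acc2_z", acc2[[3]], fs_hub),
    video_belt = channel_trace("video_belt", vb, fs_video),
    video_chest = channel_trace("video_chest", vc, fs_video),
    reference = channel_trace("reference", reference, fs_hub))
  list(recording = multimodal_recording(subject$subject_id, profile$name, ch),
       peaks = resp$peaks)
}

#' Render a belt trace as synthetic video frames
#'
#' Produces frames carrying a chessboard patch exactly the size of the
#' ROI (the high-contrast pattern attached to the seat belt). Breathing
#' moves the belt toward and away from the camera, which the simulator
#' renders as a brightness modulation of the patch's green channel, so
#' the ROI mean green value is an exact affine function of the belt
#' trace. The background gray level matches the patch's resting mean, so
#' intensity variance is maximal only when an ROI is exactly aligned
#' with the patch — the property [verify_roi] exploits. An optional
#' `offset` displaces the patch to exercise ROI re-adjustment.
#'
#' @param belt_trace A [channel_trace] sampled at the frame rate.
#' @param roi Nominal [roi_spec] the patch is aligned with.
#' @param resolution Frame size `c(height, width)` in pixels.
#' @param offset Integer `c(dx, dy)` patch displacement.
#' @param stripe Chessboard cell size in pixels.
#' @return A [frame_sequence] at `fps = belt_trace$fs`.
#' @export
simulate_frames <- function(belt_trace, roi = roi_spec(20, 20, 16, 16),
                            resolution = c(64, 64), offset = c(0L, 0L),
                            stripe = 4L) {
  stopifnot(inherits(belt_trace, "channel_trace"), inherits(roi, "roi_spec"))
  h <- resolution[1]; w <- resolution[2]
  x <- belt_trace$samples
  rng <- max(x) - min(x)
  xn <- if (rng == 0) rep(0, length(x)) else 2 * (x - min(x)) / rng - 1
  cols <- (roi$x + offset[1] + 1L):(roi$x + offset[1] + roi$w)
  rows <- (roi$y + offset[2] + 1L):(roi$y + offset[2] + roi$h)
  if (any(cols < 1L) || any(cols > w) || any(rows < 1L) || any(rows > h)) {
    stop("simulate_frames: pattern off-frame")
  }
  cell <- outer(seq_len(roi$h) - 1L, seq_len(roi$w) - 1L,
                function(r, c) ((r %/% stripe + c %/% stripe) %% 2L))
  base <- ifelse(cell == 0L, 1.0, 0.25)
  bg <- (0.6 + mean(base) * 0.7) / 3 # patch mean gray at rest
  frames <- lapply(seq_along(xn), function(i) {
    fr <- array(bg, c(h, w, 3L))
    m <- 0.7 + 0.25 * xn[i]
    fr[rows, cols, 1L] <- 0.3
    fr[rows, cols, 2L] <- base * m
    fr[rows, cols, 3L] <- 0.3
    fr
  })
  frame_sequence(frames, belt_trace$fs)
}

#' Simulate a full multi-subject driving study
#'
#' Draws `n_subjects` virtual occupants with distinct breathing rates
#' (sampled without replacement from a 12-20 breaths/min grid) and
#' simulates each in every requested scenario. Fully reproducible from
#' `master_seed`.
#'
#' @param n_subjects Number of subjects (>= 2 for LOSO use).
#' @param scenarios Scenario names; must have [default_profiles]
#'   entries.
#' @param duration_s Duration per recording, seconds.
#' @param master_seed Integer master seed.
#' @param profiles Named list of [sim_scenario_profile]s.
#' @return List of entries, one per (subject, scenario), each with
#'   `recording`, `peaks` and `subject`.
#' @export
simulate_study <- function(n_subjects, scenarios = SCENARIOS,
                           duration_s = 180, master_seed = 1L,
                           profiles = default_profiles()) {
  stopifnot(n_subjects >= 1L, all(scenarios %in% names(profiles)))
  set.seed(master_seed)
  rate_grid <- seq(12, 20, by = 0.5)
  if (n_subjects > length(rate_grid)) {
    stop("simulate_study: at most ", length(rate_grid),
         " subjects with distinct rates")
  }
  rates <- sample(rate_grid, n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    sim_subject(subject_id = sprintf("s%02d", i),
                breathing_rate_bpm = rates[i],
                rate_wander = stats::runif(1, 0.03, 0.08),
                acc_gain = stats::runif(1, 0.8, 1.2),
                piezo_gain = stats::runif(1, 0.8, 1.2),
                video_gain = stats::runif(1, 0.6, 1.0),
                video_lag_s = stats::runif(1, 0.1, 0.3),
                seed = master_seed * 131L + i)
  })
  out <- list()
  for (subj in subjects) {
    for (sc in scenarios) {
      sim <- simulate_recording(subj, profiles[[sc]], duration_s)
      out[[length(out) + 1L]] <- list(recording = sim$recording,
                                      peaks = sim$peaks, subject = subj)
    }
  }
  out
}
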