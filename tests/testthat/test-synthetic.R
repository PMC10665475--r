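test_that("simulated respiration has the requested rate and exact peaks", {
  subj <- sim_subject("s1", breathing_rate_bpm = 15, rate_wander = 0.05,
                      seed = 3)
  sim <- simulate_respiration(subj, duration_s = 60, fs = 200)
  expect_lte(abs(length(sim$peaks) - 15L), 1L)
  # peaks sit on waveform maxima: each peak sample is a local max
  x <- sim$trace$samples
  idx <- sim$peaks$indices + 1L
  interior <- idx[idx > 1 & idx < length(x)]
  expect_true(all(x[interior] >= x[interior - 1] - 1e-9 &
                    x[interior] >= x[interior + 1] - 1e-9))
  # determinism
  sim2 <- simulate_respiration(subj, 60, 200)
  expect_identical(sim$trace$samples, sim2$trace$samples)
  expect_identical(sim$peaks$indices, sim2$peaks$indices)
  # zero wander: constant inter-peak gaps
  still <- sim_subject("s2", 15, rate_wander = 0, seed = 4)
  g <- diff(simulate_respiration(still, 60, 200)$peaks$indices)
  expect_lte(max(g) - min(g), 1L)
  expect_error(sim_subject("s3", breathing_rate_bpm = 80), "physiological")
})

test_that("simulated recordings have the documented channel structure", {
  subj <- sim_subject("s1", 15, seed = 5)
  sim <- simulate_recording(subj, default_profiles()$city, duration_s = 30)
  rec <- sim$recording
  expect_setequal(names(rec$channels),
                  c("piezo", "acc1_x", "acc1_y", "acc1_z",
                    "acc2_x", "acc2_y", "acc2_z",
                    "video_belt", "video_chest", "reference"))
  expect_equal(rec$channels$piezo$fs, 100)
  expect_equal(rec$channels$video_belt$fs, 10)
  expect_equal(rec$duration_s, 30)
  # ground-truth peaks live on the 200 Hz unified timeline
  expect_equal(sim$peaks$fs, 200)
  expect_true(all(sim$peaks$indices < 30 * 200))
})

test_that("noise-free accelerometer carries the clean respiration", {
  subj <- sim_subject("s1", 15, seed = 6)
  quiet <- sim_scenario_profile("city", noise_gain = 0,
                                transient_rate_per_min = 0, drift_gain = 0)
  sim <- simulate_recording(subj, quiet, duration_s = 60)
  clean <- simulate_respiration(subj, 60, 200)$trace$samples
  clean_hub <- clean[seq(1, length(clean), by = 2)]
  pc <- pca_axis_combine(sim$recording$channels$acc1_x,
                         sim$recording$channels$acc1_y,
                         sim$recording$channels$acc1_z)
  expect_gt(abs(cor(pc$samples, clean_hub)), 0.99)
})

test_that("the seat accelerometer carries no respiration", {
  subj <- sim_subject("s1", 15, seed = 7)
  sim <- simulate_recording(subj, default_profiles()$city, duration_s = 120)
  clean <- simulate_respiration(subj, 120, 200)$trace$samples
  clean_hub <- clean[seq(1, length(clean), by = 2)]
  ch <- sim$recording$channels
  # in the respiration band, the seat channel is uncorrelated with the
  # chest movement ...
  a2 <- pca_axis_combine(bandpass(ch$acc2_x, 0.1, 0.7),
                         bandpass(ch$acc2_y, 0.1, 0.7),
                         bandpass(ch$acc2_z, 0.1, 0.7))
  expect_lt(abs(cor(a2$samples, clean_hub)), 0.1)
  # ... and its smoothed spectrum shows no peak at the breathing
  # frequency, unlike the seat-belt channel
  f_resp <- 15 / 60
  psd_at <- function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = 100), spans = c(5, 5),
                            taper = 0, plot = FALSE, detrend = TRUE)
    sp$spec[which.min(abs(sp$freq - f_resp))]
  }
  expect_lt(psd_at(ch$acc2_x$samples) / psd_at(ch$acc1_x$samples), 0.2)
})

test_that("scenario noise energies follow the profile gain ordering", {
  subj <- sim_subject("s1", 15, seed = 8)
  profs <- default_profiles()
  energy <- vapply(profs[c("highway", "city", "countryside")], function(p) {
    sim <- simulate_recording(subj, p, duration_s = 30)
    mean(sim$recording$channels$acc2_x$samples^2)
  }, numeric(1))
  # gains 0.7 < 1.0 < 1.3 must order the noise-only channel energies
  expect_true(energy[["highway"]] < energy[["city"]])
  expect_true(energy[["city"]] < energy[["countryside"]])
})

test_that("vehicle noise overlaps the respiration band", {
  # the denoising premise: the shared noise (body-sway resonance) has
  # substantial energy inside the respiration band
  set.seed(9)
  x <- respfusion:::vehicle_noise(60 * 200, 200, default_profiles()$city)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 200), taper = 0,
                          plot = FALSE)
  inband <- sum(sp$spec[sp$freq >= 0.1 & sp$freq <= 0.7])
  expect_gt(inband / sum(sp$spec), 0.05)
})

test_that("synthetic frames recover the belt trace through the video path", {
  fps <- 10
  t <- seq(0, 20, by = 1 / fps)[-201]
  belt <- channel_trace("belt", sin(2 * pi * 0.25 * t), fps)
  roi <- roi_spec(20, 20, 16, 16)
  seqs <- simulate_frames(belt, roi = roi, resolution = c(64, 64))
  tr <- frames_to_trace(seqs, roi)
  # affine recovery: high linear correlation with the input trace
  expect_gt(cor(tr$samples, belt$samples), 0.98)
  # constant trace: identical frames
  flatseq <- simulate_frames(channel_trace("b", rep(0.5, 5), fps), roi = roi,
                             resolution = c(64, 64))
  expect_identical(flatseq$frames[[1]], flatseq$frames[[5]])
})

test_that("study simulation is deterministic with distinct subjects", {
  st <- simulate_study(6, scenarios = SCENARIOS, duration_s = 10,
                       master_seed = 11)
  expect_length(st, 18L)
  scens <- vapply(st, function(e) e$recording$scenario, character(1))
  expect_equal(sum(scens == "city"), 6L)
  rates <- unique(vapply(st, function(e) e$subject$breathing_rate_bpm,
                         numeric(1)))
  expect_length(rates, 6L) # distinct breathing rates
  st2 <- simulate_study(6, scenarios = SCENARIOS, duration_s = 10,
                        master_seed = 11)
  expect_identical(st[[5]]$recording$channels$piezo$samples,
                   st2[[5]]$recording$channels$piezo$samples)
  st3 <- simulate_study(6, scenarios = SCENARIOS, duration_s = 10,
                        master_seed = 12)
  expect_false(identical(st[[5]]$recording$channels$piezo$samples,
                         st3[[5]]$recording$channels$piezo$samples))
})

test_that("preprocessing aligns simulated channels on the unified timeline", {
  study <- simulate_study(1, scenarios = "city", duration_s = 30,
                          master_seed = 13)
  cfg <- pipeline_config()
  rec <- preprocess_recording(study[[1]]$recording, cfg)
  expect_setequal(names(rec$channels),
                  c("piezo", "acc", "video_belt", "video_chest", "reference"))
  for (ch in rec$channels) expect_equal(ch$fs, 200)
  lens <- vapply(rec$channels, length, integer(1))
  expect_equal(length(unique(lens)), 1L)
  # detected reference peaks approximate the ground truth
  det <- detect_reference_peaks(rec$channels$reference, cfg)
  truth <- study[[1]]$peaks$indices
  expect_lte(abs(length(det) - length(truth)), 1L)
  matched <- vapply(det$indices, function(i) min(abs(truth - i)), numeric(1))
  expect_lt(median(matched), 25) # within ~0.125 s of truth
})
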