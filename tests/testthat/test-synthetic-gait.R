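test_that("trial length, determinism and null-signal cases", {
  # floor(90 * 142.85) samples for a 90 s trial at the timestep rate
  p <- subject_profile(rng_seed = 3)
  tr <- generate_trial(p, trial_spec("N", 0.54, duration = 90))
  expect_equal(length(tr$samples), 12856L)
  expect_true(all(tr$labels == "N"))

  # same (profile, spec) twice -> identical traces
  tr2 <- generate_trial(p, trial_spec("N", 0.54, duration = 90))
  expect_identical(tr$samples, tr2$samples)

  # all-zero profile and zero noise -> all-zero trace
  p0 <- subject_profile(harmonic_amplitudes = rep(0, 4),
                        impact_amplitude = 0, noise_sd = 0)
  tr0 <- generate_trial(p0, trial_spec("N", 0.54, duration = 10))
  expect_equal(tr0$samples, rep(0, length(tr0$samples)))
})

test_that("invalid speeds and rates are rejected", {
  expect_error(trial_spec("N", speed = 1.1), "unknown treadmill speed")
  expect_error(trial_spec("N", sample_rate = 1000), "14285 or 142.85")
  expect_error(trial_spec("N", duration = 5, discard_head = 10))
})

test_that("trace amplitude and spectral content match the gait envelope", {
  # RMS ~1 g scale across all five speeds; >= 90% of non-impact power
  # in the 0.5-15 Hz band
  for (v in gait_speeds()) {
    p <- subject_profile(rng_seed = 11)
    tr <- generate_trial(p, trial_spec("N", v, duration = 30))
    rms <- sqrt(mean(tr$samples^2))
    expect_gt(rms, 0.3)
    expect_lt(rms, 3)

    p_noimp <- subject_profile(rng_seed = 11, impact_amplitude = 0)
    trh <- generate_trial(p_noimp, trial_spec("N", v, duration = 30))
    sp <- stats::spec.pgram(stats::ts(trh$samples, frequency = 142.85),
                            taper = 0, plot = FALSE, detrend = TRUE)
    inband <- sp$freq >= 0.5 & sp$freq <= 15
    expect_gt(sum(sp$spec[inband]) / sum(sp$spec), 0.9)
  }
})

test_that("pattern effects: N is identity, TO boosts even harmonics", {
  p <- subject_profile()
  wf <- base_waveform(p, 0.54)
  expect_identical(apply_pattern_effects(wf, "N"), wf)

  to <- apply_pattern_effects(wf, "TO")
  expect_equal(to$harm_amp[c(2, 4)], wf$harm_amp[c(2, 4)] * 1.5)
  expect_equal(to$harm_amp[c(1, 3)], wf$harm_amp[c(1, 3)])
  expect_gt(to$dc, 0)

  totl <- apply_pattern_effects(wf, "TOTL")
  expect_equal(totl$harm_amp, to$harm_amp)       # TL changes no amplitude
  expect_true(totl$impact_reversed)
})

test_that("TL matches the N power spectrum but flips the phase coupling", {
  p <- subject_profile(rng_seed = 0)
  trN <- generate_trial(p, trial_spec("N", 0.54, duration = 60))
  trTL <- generate_trial(p, trial_spec("TL", 0.54, duration = 60))

  # smoothed, tapered periodograms agree within 5% on the bins that
  # jointly carry 90% of the N-trial power (outside that support the
  # bins hold only leakage-skirt interference at ~1e-4 of peak power)
  sN <- stats::spec.pgram(stats::ts(trN$samples, frequency = 142.85),
                          spans = c(15, 15), taper = 0.5, plot = FALSE)
  sT <- stats::spec.pgram(stats::ts(trTL$samples, frequency = 142.85),
                          spans = c(15, 15), taper = 0.5, plot = FALSE)
  rel <- abs(sT$spec - sN$spec) / ((sT$spec + sN$spec) / 2)
  ord <- order(-sN$spec)
  support <- ord[cumsum(sN$spec[ord]) / sum(sN$spec) <= 0.90]
  expect_lt(max(rel[support]), 0.05)

  # the third-order moment (triad phase closure) reverses sign
  expect_gt(third_moment(trN$samples), 0)
  expect_lt(third_moment(trTL$samples), 0)
})

test_that("a linear classifier on raw windows is blind to TL", {
  # ridge linear classifier on raw 1 s windows, trained on 3 subjects
  # and tested on 2 held-out subjects: TL-vs-N AUC stays near chance
  win <- 143L   # 1 s at the timestep rate
  make_windows <- function(subjects, master_seed = 5) {
    X <- NULL; y <- NULL
    for (i in subjects) for (pat in c("N", "TL")) {
      prof <- memsgait:::draw_subject_profile(master_seed, i)
      prof$rng_seed <- memsgait:::hash_seed(master_seed, i,
                                            match(pat, gait_patterns()))
      tr <- generate_trial(prof, trial_spec(pat, 0.54, duration = 30))
      starts <- seq(1, length(tr$samples) - win, by = win)
      W <- vapply(starts, function(s0) tr$samples[s0:(s0 + win - 1)],
                  numeric(win))
      X <- cbind(X, W)
      y <- c(y, rep(as.numeric(pat == "TL"), length(starts)))
    }
    list(X = rbind(1, X), y = y)
  }
  tr <- make_windows(1:3)
  te <- make_windows(4:5)
  W <- ridge_train(tr$X, rbind(tr$y), beta = 1)
  sc <- as.numeric(W %*% te$X)
  expect_lt(roc_auc(sc, te$y)$auc, 0.65)
})

test_that("cohort generation is a pure function of the master seed", {
  c1 <- generate_cohort(2, speeds = c(0.45, 0.63), patterns = c("N", "TO"),
                        master_seed = 9, duration = 10)
  c2 <- generate_cohort(2, speeds = c(0.45, 0.63), patterns = c("N", "TO"),
                        master_seed = 9, duration = 10)
  expect_equal(nrow(c1$manifest), 2 * 2 * 2)
  expect_identical(lapply(c1$trials, `[[`, "samples"),
                   lapply(c2$trials, `[[`, "samples"))
  # label balance at fixed speed
  tab <- table(c1$manifest$pattern[c1$manifest$speed == 0.45])
  expect_true(all(tab == tab[1]))

  c3 <- generate_cohort(2, speeds = c(0.45, 0.63), patterns = c("N", "TO"),
                        master_seed = 10, duration = 10)
  expect_false(identical(c1$trials[[1]]$samples, c3$trials[[1]]$samples))

  expect_error(generate_cohort(2, speeds = numeric(0)), "non-empty")
  # the emulated protocol: 20 sequences per participant
  g <- expand.grid(pattern = gait_patterns(), speed = gait_speeds())
  expect_equal(nrow(g), 20L)
})

test_that("sensor distortion has the stated frequency response", {
  rate <- 14285
  t <- (0:(rate / 5 - 1)) / rate

  # flat settings -> scaled identity
  tone <- accel_trace(sin(2 * pi * 200 * t), rate)
  flat <- sensor_distortion(tone, sensitivity_low = 0.07,
                            sensitivity_high = 0.07,
                            resonance_freq = 300, resonance_gain_db = 0)
  expect_equal(flat$samples, 0.07 * tone$samples, tolerance = 1e-9)

  # 6 dB resonance doubles a tone at the resonance frequency
  peaked <- sensor_distortion(tone, sensitivity_low = 0.07,
                              sensitivity_high = 0.07,
                              resonance_freq = 200, resonance_gain_db = 6)
  ratio <- max(abs(peaked$samples)) / max(abs(flat$samples))
  expect_equal(ratio, 2, tolerance = 0.05)

  # DC offset maps through the low-frequency sensitivity
  dc <- accel_trace(rep(0.5, length(t)), rate)
  out <- sensor_distortion(dc, sensitivity_low = 0.05,
                           sensitivity_high = 0.1, resonance_freq = 200,
                           resonance_gain_db = 6)
  expect_equal(mean(out$samples), 0.05 * 0.5, tolerance = 1e-6)

  # resonance above Nyquist rejected
  expect_error(sensor_distortion(tone, resonance_freq = 8000),
               "Nyquist")
})
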