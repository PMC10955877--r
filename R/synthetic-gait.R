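#' Treadmill speeds of the gait protocol
#'
#' The five belt speeds (m/s) used by the walking protocol the generator
#' emulates: slow speeds representative of a population with knee pain,
#' spanning roughly +/- 33% around the 0.54 m/s midpoint.
#'
#' @return numeric vector of speeds in m/s.
#' @export
gait_speeds <- function() c(0.36, 0.45, 0.54, 0.63, 0.72)

#' Synthetic subject profile
#'
#' Per-subject parameters of the harmonic gait-waveform model. A subject's
#' foot acceleration under normal gait is modelled as a harmonic series at
#' the step frequency, a heel-strike impulse train convolved with a decaying
#' oscillation, and additive white measurement noise. All amplitudes are in
#' units of standard gravity (g).
#'
#' @param subject_id identifier (integer or string).
#' @param base_step_frequency step frequency in Hz at the reference speed
#'   0.54 m/s; scaled to other speeds by the square-root walk-ratio rule.
#' @param harmonic_amplitudes nonnegative amplitudes (g) of harmonics
#'   1..K of the step frequency, at the reference speed.
#' @param harmonic_phases phases (rad) of the harmonics.
#' @param impact_amplitude peak amplitude (g) of the heel-strike transient
#'   at the reference speed.
#' @param impact_freq_hz centre ringing frequency (Hz) of the heel-strike
#'   transient (typically 20-60 Hz).
#' @param impact_sharpness dimensionless; larger values give a shorter
#'   transient (Gaussian width = 0.02 s / impact_sharpness).
#' @param timing_jitter cycle-to-cycle standard deviation of heel-strike
#'   timing, as a fraction of the gait cycle.
#' @param impact_amp_jitter per-strike coefficient of variation of the
#'   transient amplitude.
#' @param noise_sd standard deviation (g) of the additive measurement noise.
#' @param rng_seed integer seed controlling all randomness of a trial
#'   generated from this profile.
#' @return object of class `subject_profile`.
#' @seealso [generate_trial()], [generate_cohort()]
#' @export
subject_profile <- function(subject_id = 1L,
                            base_step_frequency = 1.6,
                            harmonic_amplitudes = c(0.55, 0.28, 0.14, 0.07),
                            harmonic_phases = rep(0, length(harmonic_amplitudes)),
                            impact_amplitude = 0.9,
                            impact_freq_hz = 35,
                            impact_sharpness = 1,
                            timing_jitter = 0.02,
                            impact_amp_jitter = 0.1,
                            noise_sd = 0.02,
                            rng_seed = 1L) {
  stopifnot(base_step_frequency > 0,
            all(harmonic_amplitudes >= 0),
            length(harmonic_phases) == length(harmonic_amplitudes),
            impact_amplitude >= 0, impact_freq_hz > 0,
            impact_sharpness > 0, noise_sd >= 0)
  structure(list(
    subject_id = subject_id,
    base_step_frequency = base_step_frequency,
    harmonic_amplitudes = harmonic_amplitudes,
    harmonic_phases = harmonic_phases,
    impact_amplitude = impact_amplitude,
    impact_freq_hz = impact_freq_hz,
    impact_sharpness = impact_sharpness,
    timing_jitter = timing_jitter,
    impact_amp_jitter = impact_amp_jitter,
    noise_sd = noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "subject_profile")
}

#' Trial specification
#'
#' One treadmill sequence: a gait pattern walked at one belt speed for a
#' fixed duration. The first `discard_head` seconds correspond to the
#' settling period of the walking protocol and are recorded in the trace
#' provenance for downstream discarding.
#'
#' @param pattern gait pattern code, see [gait_patterns()].
#' @param speed belt speed in m/s; must be one of [gait_speeds()].
#' @param duration sequence duration in seconds.
#' @param discard_head head period in seconds flagged for discarding.
#' @param sample_rate sampling rate in Hz; either 14285 (raw acquisition)
#'   or 142.85 (node-rate, i.e. classifier timestep rate).
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(pattern = "N", speed = 0.54, duration = 90,
                       discard_head = min(10, duration / 9),
                       sample_rate = 142.85) {
  pattern <- match_pattern(pattern)
  stopifnot(length(pattern) == 1L, length(speed) == 1L)
  if (!any(abs(speed - gait_speeds()) < 1e-9)) {
    stop("unknown treadmill speed: ", speed,
         " (must be one of ", paste(gait_speeds(), collapse = ", "), ")")
  }
  if (!any(abs(sample_rate - c(14285, 142.85)) < 1e-9)) {
    stop("sample_rate must be 14285 or 142.85 Hz")
  }
  stopifnot(duration > discard_head, discard_head >= 0)
  structure(list(pattern = pattern, speed = speed, duration = duration,
                 discard_head = discard_head, sample_rate = sample_rate),
            class = "trial_spec")
}

#' Acceleration trace container
#'
#' @param samples numeric vector of accelerations (g).
#' @param sample_rate sampling rate in Hz.
#' @param pattern gait pattern label, constant over the trial.
#' @param provenance list carrying the trial spec, subject id and seed.
#' @return object of class `accel_trace` with fields `samples`,
#'   `sample_rate`, `pattern`, `labels` (per-sample pattern codes) and
#'   `provenance`.
#' @export
accel_trace <- function(samples, sample_rate, pattern = "N",
                        provenance = list()) {
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  pattern <- match_pattern(pattern)
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 pattern = pattern,
                 labels = rep(pattern, length(samples)),
                 provenance = provenance),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %.2f Hz (%.2f s), pattern %s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$pattern))
  invisible(x)
}

#' @export
length.accel_trace <- function(x) length(x$samples)

# Step frequency at a given belt speed: square-root walk-ratio scaling
# around the 0.54 m/s reference.
step_frequency <- function(profile, speed) {
  profile$base_step_frequency * sqrt(speed / 0.54)
}

# Acceleration amplitudes grow sublinearly with belt speed.
amplitude_scale <- function(speed) (speed / 0.54)^0.7

#' Normal-gait waveform parameters for one trial
#'
#' Assembles the parametric description of the N-pattern waveform for a
#' subject at a given speed. Pattern effects ([apply_pattern_effects()])
#' operate on this parameter object before rendering, so that toe-out and
#' trunk-lean act as controlled interventions on the harmonic structure.
#'
#' @param profile a [subject_profile()].
#' @param speed belt speed (m/s).
#' @return object of class `gait_waveform`: step frequency, harmonic
#'   amplitudes/phases, DC offset, and heel-strike transient parameters.
#' @export
base_waveform <- function(profile, speed) {
  scale <- amplitude_scale(speed)
  structure(list(
    step_freq = step_frequency(profile, speed),
    harm_amp = profile$harmonic_amplitudes * scale,
    harm_phase = profile$harmonic_phases,
    dc = 0,
    impact_amplitude = profile$impact_amplitude * scale,
    impact_freq_hz = profile$impact_freq_hz,
    impact_width_s = 0.02 / profile$impact_sharpness,
    impact_reversed = FALSE
  ), class = "gait_waveform")
}

#' Apply gait-pattern effects to a normal-gait waveform
#'
#' Encodes the class structure of the four gait patterns:
#'
#' * `N`: identity.
#' * `TO` (toe-out): the outward foot rotation changes the gravity
#'   projection on the sensing axis (small DC offset) and boosts and
#'   phase-shifts the even step harmonics. These are first- and
#'   second-order changes, detectable by a linear classifier at fixed
#'   speed.
#' * `TL` (trunk-lean): re-codes the class in cross-harmonic phase
#'   coupling (the even-harmonic phases are flipped by pi, reversing the
#'   waveform's triad phase closures and hence its skewness) and in the
#'   temporal asymmetry of the heel-strike transient (time-reversed
#'   impulse response). Both edits are phase-only: the per-frequency power
#'   spectrum of a TL trial matches the N trial, so no linear functional
#'   of a raw window separates TL from N; nonlinear classifiers can read
#'   the flipped third-order moments.
#' * `TOTL`: composition of both.
#'
#' @param base a `gait_waveform` describing the N pattern
#'   (see [base_waveform()]).
#' @param pattern gait pattern code.
#' @param to_even_gain amplitude gain applied by TO to even harmonics.
#' @param to_phase_shift phase shift (rad) applied by TO to even harmonics.
#' @param to_dc_offset DC offset (g) added by TO.
#' @return modified `gait_waveform`.
#' @export
apply_pattern_effects <- function(base, pattern,
                                  to_even_gain = 1.5,
                                  to_phase_shift = 0.6,
                                  to_dc_offset = 0.08) {
  stopifnot(inherits(base, "gait_waveform"))
  pattern <- match_pattern(pattern)
  wf <- base
  even <- seq_along(wf$harm_amp) %% 2L == 0L
  if (pattern %in% c("TO", "TOTL")) {
    wf$harm_amp[even] <- wf$harm_amp[even] * to_even_gain
    wf$harm_phase[even] <- wf$harm_phase[even] + to_phase_shift
    wf$dc <- wf$dc + to_dc_offset
  }
  if (pattern %in% c("TL", "TOTL")) {
    wf$harm_phase[even] <- wf$harm_phase[even] + pi
    wf$impact_reversed <- TRUE
  }
  wf
}

# Heel-strike impulse response: Gaussian-windowed chirp around the impact
# ringing frequency. The Gaussian spectral envelope keeps the transient's
# energy out of the 0.5-15 Hz gait band, so it does not interfere with the
# gait harmonics at shared frequency bins; the chirp makes the transient
# temporally asymmetric. Time reversal (trunk-lean) flips the chirp
# direction while exactly preserving the magnitude spectrum.
impact_kernel <- function(freq_hz, decay_s, sample_rate, reversed = FALSE,
                          chirp_span_hz = 15) {
  sigma <- decay_s
  u <- seq(-3 * sigma, 3 * sigma, by = 1 / sample_rate)
  kappa <- pi * chirp_span_hz / (2 * sigma)
  h <- exp(-(u / sigma)^2) * sin(2 * pi * freq_hz * u + kappa * u^2)
  if (reversed) h <- rev(h)
  h
}

#' Generate one labelled acceleration trial
#'
#' Renders a synthetic foot-acceleration trace for one subject walking one
#' gait pattern at one treadmill speed: harmonic gait waveform at the
#' (speed-scaled) step frequency, heel-strike impulse train convolved with
#' a decaying oscillation, and white measurement noise. The generation is a
#' pure function of `(profile$rng_seed, spec)`; the random streams do not
#' depend on the gait pattern, so two trials differing only in `pattern`
#' share their noise and timing jitter (the pattern is a controlled
#' intervention).
#'
#' @param profile a [subject_profile()].
#' @param spec a [trial_spec()].
#' @return an [accel_trace()].
#' @export
generate_trial <- function(profile, spec) {
  stopifnot(inherits(profile, "subject_profile"), inherits(spec, "trial_spec"))
  n <- floor(spec$duration * spec$sample_rate)
  rate <- spec$sample_rate
  wf_n <- base_waveform(profile, spec$speed)

  # Draw every random quantity before pattern effects, in a fixed order,
  # from a private RNG state (pattern-independent streams).
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(profile$rng_seed)
  n_strikes <- ceiling(spec$duration * wf_n$step_freq) + 2L
  strike_jit <- stats::rnorm(n_strikes, 0, profile$timing_jitter)
  strike_amp <- 1 + stats::rnorm(n_strikes, 0, profile$impact_amp_jitter)
  noise <- stats::rnorm(n, 0, profile$noise_sd)

  wf <- apply_pattern_effects(wf_n, spec$pattern)
  t <- (seq_len(n) - 1) / rate

  x <- rep(wf$dc, n)
  for (k in seq_along(wf$harm_amp)) {
    if (wf$harm_amp[k] > 0) {
      x <- x + wf$harm_amp[k] *
        cos(2 * pi * k * wf$step_freq * t + wf$harm_phase[k])
    }
  }

  if (wf$impact_amplitude > 0) {
    strike_t <- (seq_len(n_strikes) - 1 + strike_jit) / wf$step_freq
    idx <- round(strike_t * rate) + 1L
    keep <- idx >= 1L & idx <= n
    train <- numeric(n)
    train[idx[keep]] <- train[idx[keep]] +
      wf$impact_amplitude * strike_amp[keep]
    h <- impact_kernel(wf$impact_freq_hz, wf$impact_width_s, rate,
                       reversed = wf$impact_reversed)
    x <- x + stats::convolve(train, rev(h), type = "open")[seq_len(n)]
  }

  x <- x + noise
  accel_trace(x, rate, spec$pattern,
              provenance = list(spec = spec,
                                subject_id = profile$subject_id,
                                rng_seed = profile$rng_seed))
}

#' Non-ideal sensor front-end distortion
#'
#' Emulates the imperfect transfer function of a prototype accelerometer:
#' a frequency-dependent sensitivity interpolating between a low-frequency
#' and an in-band high-frequency value over the sensor bandwidth, plus one
#' in-band resonant peak. Applied as a zero-phase frequency-domain gain.
#'
#' @param trace an [accel_trace()] at the raw rate.
#' @param sensitivity_low sensitivity at DC (V/g).
#' @param sensitivity_high sensitivity at/above `bandwidth` (V/g).
#' @param resonance_freq resonance frequency (Hz); must be below Nyquist.
#' @param resonance_gain_db peak gain (dB) added at the resonance.
#' @param bandwidth sensor bandwidth (Hz) over which sensitivity ramps.
#' @param resonance_width width (Hz) of the (Gaussian-in-dB) resonance;
#'   defaults to a tenth of the resonance frequency.
#' @return an `accel_trace` whose samples are the distorted signal (V).
#' @export
sensor_distortion <- function(trace, sensitivity_low = 0.05,
                              sensitivity_high = 0.1,
                              resonance_freq = 200, resonance_gain_db = 6,
                              bandwidth = 400,
                              resonance_width = resonance_freq / 10) {
  stopifnot(inherits(trace, "accel_trace"))
  nyq <- trace$sample_rate / 2
  if (resonance_freq > nyq) {
    stop("resonance_freq (", resonance_freq, " Hz) exceeds Nyquist (",
         nyq, " Hz)")
  }
  n <- length(trace$samples)
  f <- abs((seq_len(n) - 1) / n * trace$sample_rate)
  f <- pmin(f, trace$sample_rate - f)   # two-sided frequency magnitude
  base <- sensitivity_low +
    (sensitivity_high - sensitivity_low) * pmin(f / bandwidth, 1)
  peak_db <- resonance_gain_db *
    exp(-((f - resonance_freq) / (resonance_width / 2))^2)
  H <- base * 10^(peak_db / 20)
  y <- Re(stats::fft(stats::fft(trace$samples) * H, inverse = TRUE)) / n
  out <- trace
  out$samples <- y
  out$provenance$distortion <- list(sensitivity_low = sensitivity_low,
                                    sensitivity_high = sensitivity_high,
                                    resonance_freq = resonance_freq,
                                    resonance_gain_db = resonance_gain_db)
  out
}

# Deterministic 31-bit seed mixing for counter-based trial seeds.
hash_seed <- function(...) {
  v <- c(...)
  x <- 104729
  for (u in v) {
    x <- (x * 69069 + as.numeric(u) + 12345) %% 2147483629
  }
  as.integer(x) + 1L
}

#' Generate a cohort of labelled gait trials
#'
#' One trial per (subject, speed, pattern). Subject profiles are drawn from
#' lognormal/normal jitter distributions around the default profile; every
#' trial receives a counter-hashed seed derived from `master_seed`, so the
#' whole cohort is a pure function of `master_seed`.
#'
#' @param n_subjects number of synthetic subjects (the emulated protocol
#'   used 10).
#' @param speeds belt speeds (subset of [gait_speeds()]).
#' @param patterns gait patterns to include.
#' @param master_seed integer master seed.
#' @param duration trial duration (s).
#' @param sample_rate sampling rate (Hz).
#' @param out_dir optional directory; when given, trace CSVs and a JSON
#'   manifest are written there.
#' @return object of class `gait_cohort`: list with `trials` (list of
#'   [accel_trace()]), `manifest` (data.frame of subject, speed, pattern,
#'   seed) and `master_seed`.
#' @export
generate_cohort <- function(n_subjects = 10, speeds = gait_speeds(),
                            patterns = gait_patterns(), master_seed = 1L,
                            duration = 90, sample_rate = 142.85,
                            out_dir = NULL) {
  stopifnot(n_subjects >= 1)
  if (length(speeds) == 0L || length(patterns) == 0L) {
    stop("speeds and patterns must be non-empty")
  }
  patterns <- match_pattern(patterns)
  grid <- expand.grid(pattern = patterns, speed = speeds,
                      subject = seq_len(n_subjects),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  trials <- vector("list", nrow(grid))
  seeds <- integer(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    i <- grid$subject[r]
    j <- (r - 1L) %% (length(speeds) * length(patterns))  # trial index
    seeds[r] <- hash_seed(master_seed, i, j)
    prof <- draw_subject_profile(master_seed, i)
    prof$rng_seed <- seeds[r]
    spec <- trial_spec(grid$pattern[r], grid$speed[r], duration = duration,
                       sample_rate = sample_rate)
    trials[[r]] <- generate_trial(prof, spec)
  }
  manifest <- data.frame(subject = grid$subject, speed = grid$speed,
                         pattern = grid$pattern, seed = seeds,
                         stringsAsFactors = FALSE)
  cohort <- structure(list(trials = trials, manifest = manifest,
                           master_seed = as.integer(master_seed)),
                      class = "gait_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

# Subject-level parameter jitter: multiplicative lognormal for scales,
# additive normal for phases.
draw_subject_profile <- function(master_seed, i) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(hash_seed(master_seed, i, -1))
  d <- subject_profile()
  lnorm <- function(cv) exp(stats::rnorm(1, 0, cv))
  subject_profile(
    subject_id = i,
    base_step_frequency = d$base_step_frequency * lnorm(0.08),
    harmonic_amplitudes = d$harmonic_amplitudes *
      exp(stats::rnorm(length(d$harmonic_amplitudes), 0, 0.15)),
    harmonic_phases = d$harmonic_phases +
      stats::rnorm(length(d$harmonic_phases), 0, 0.1),
    impact_amplitude = d$impact_amplitude * lnorm(0.2),
    impact_freq_hz = d$impact_freq_hz * lnorm(0.15),
    impact_sharpness = d$impact_sharpness * lnorm(0.15),
    rng_seed = hash_seed(master_seed, i, -1)
  )
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trials (%d subjects), master_seed %d\n",
              nrow(x$manifest), length(unique(x$manifest$subject)),
              x$master_seed))
  invisible(x)
}
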