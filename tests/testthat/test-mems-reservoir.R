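test_that("proof-mass statics: closed-form displacement and clipping", {
  p <- proof_mass_params()
  rate <- 14285
  # constant 1 g: steady state |x| = m g0 / k ~ 7.07e-8 m
  x <- proof_mass_response(rep(1, 3 * rate), p, sample_rate = rate)
  expect_equal(abs(x[length(x)]), 49e-9 * 9.81 / 6.8, tolerance = 1e-3)

  # zero input -> identically zero
  x0 <- proof_mass_response(rep(0, 1000), p, sample_rate = rate)
  expect_equal(x0, rep(0, 1000))

  # constant 100 g: static solution 7.07e-6 m exceeds the stopper limit,
  # displacement clips at 5e-6 m
  xc <- proof_mass_response(rep(100, 2 * rate), p, sample_rate = rate)
  expect_equal(abs(xc[length(xc)]), 5e-6, tolerance = 1e-6)
  expect_lte(max(abs(xc)), 5e-6 + 1e-12)

  expect_error(proof_mass_response(c(1, NA, 2), p, sample_rate = rate),
               "non-finite")
})

test_that("envelope free decay follows exp(-t/tau)", {
  # the decay of |A| is gamma-independent (the cubic term only rotates
  # the phase); in the linear beam the discretization is near-exact,
  # with nonlinearity a small phase-coupling step error remains
  dt <- 1e-5
  n <- 50
  for (cfg in list(list(b = beam_params(duffing_coefficient = 0),
                        tol = 1e-5),
                   list(b = beam_params(), tol = 1e-3))) {
    A <- 2 + 1i
    for (i in seq_len(n)) {
      A <- duffing_envelope_step(A, drive = 0, detuning = 5000,
                                 b = cfg$b, dt = dt)
    }
    expect_equal(Mod(A), Mod(2 + 1i) * exp(-n * dt / cfg$b$decay_time),
                 tolerance = cfg$tol)
  }
})

test_that("linear-limit steady states match the Lorentzian closed form", {
  b <- beam_params(duffing_coefficient = 0)
  F <- 5000
  tau <- b$decay_time
  detunings <- seq(-2e4, 2e4, length.out = 20)
  for (d in detunings) {
    A <- duffing_settle(F, d, b, settle_time = 40 * tau)
    expected <- (F / 2) * tau / sqrt(1 + (d * tau)^2)
    expect_equal(Mod(A), expected, tolerance = 1e-4)
  }
})

test_that("stiffening: peak shifts up with drive and sweeps show hysteresis", {
  b <- beam_params()
  grid <- seq(493.4e3, 501.0e3, by = 200)
  up_lo <- duffing_sweep(b, drive_voltage = 30, freq_grid = grid)
  up_hi <- duffing_sweep(b, drive_voltage = 100, freq_grid = grid)
  # peak frequency increases with drive amplitude
  expect_gt(up_hi$freq[which.max(up_hi$amplitude)],
            up_lo$freq[which.max(up_lo$amplitude)])
  # up vs down sweeps disagree over a nonempty interval at high drive
  dn_hi <- duffing_sweep(b, drive_voltage = 100, freq_grid = grid,
                         direction = "down")
  dn_hi <- dn_hi[order(dn_hi$freq), ]
  rel <- abs(up_hi$amplitude - dn_hi$amplitude) /
    pmax(up_hi$amplitude, dn_hi$amplitude)
  expect_gt(sum(rel > 0.05), 0)
  # low drive is single-valued: no hysteresis
  dn_lo <- duffing_sweep(b, drive_voltage = 30, freq_grid = grid,
                         direction = "down")
  dn_lo <- dn_lo[order(dn_lo$freq), ]
  rel_lo <- abs(up_lo$amplitude - dn_lo$amplitude) /
    pmax(up_lo$amplitude, dn_lo$amplitude)
  expect_lt(max(rel_lo), 0.01)
})

test_that("multiplex timing: N*theta = 7 ms and 142.857 Hz update rate", {
  cfg <- multiplex_config()
  expect_equal(timestep_period(cfg), 7e-3, tolerance = 1e-12)
  expect_equal(update_rate(cfg) * 7e-3, 1, tolerance = 1e-6)
  expect_lt(cfg$node_separation, beam_params()$decay_time)
})

test_that("multiplex symmetry, sensitivity and feedback memory", {
  cfg <- multiplex_config(n_nodes = 20)
  b <- beam_params()
  p <- proof_mass_params()

  # no input, no feedback: after settling all nodes sit at the same
  # constant-drive fixed point
  cfg0 <- cfg; cfg0$input_gain <- 0; cfg0$feedback_gain <- 0
  st <- multiplex(numeric(20), cfg0, b, p)
  for (i in 1:10) st <- multiplex(numeric(20), cfg0, b, p,
                                  prev_nodes = st$activations, A0 = st$A)
  a <- st$activations
  expect_lt(max(abs(a - mean(a))) / mean(a), 1e-6)

  # one-sample input difference changes the activations
  d1 <- c(numeric(10), 1e-7, numeric(9))
  s1 <- multiplex(d1, cfg, b, p, A0 = st$A)
  s2 <- multiplex(numeric(20), cfg, b, p, A0 = st$A)
  expect_false(isTRUE(all.equal(s1$activations, s2$activations)))

  # with feedback off, a timestep's activations do not depend on the
  # previous timestep's node values (memoryless beyond beam settling)
  cfgnf <- cfg; cfgnf$feedback_gain <- 0
  r1 <- multiplex(d1, cfgnf, b, p, prev_nodes = runif(20), A0 = st$A)
  r2 <- multiplex(d1, cfgnf, b, p, prev_nodes = runif(20), A0 = st$A)
  expect_equal(r1$activations, r2$activations, tolerance = 1e-12)

  # pull-in fault when the gap modulation reaches unity
  expect_error(multiplex(rep(9e-6, 20), cfg, b, p), "pull-in")
})

test_that("run_reservoir timestep count, determinism and settling", {
  cfg <- multiplex_config(n_nodes = 10, node_separation = 7e-4)
  b <- beam_params()
  p <- proof_mass_params()

  # M = floor(duration / (N * theta))
  tr <- accel_trace(rep(0, floor(9 * 142.85)), 142.85)
  rt <- run_reservoir(tr, cfg, b, p)
  expect_equal(ncol(rt$activations),
               floor(length(tr$samples) / 142.85 / (10 * 7e-4)))
  expect_true(all(rt$activations >= 0))

  # zero acceleration: all timesteps' node vectors identical after settling
  A <- rt$activations
  late <- A[, (ncol(A) - 5):ncol(A)]
  expect_lt(max(abs(late - late[, 1])) / mean(late), 1e-6)

  # determinism on a nonzero input
  p5 <- subject_profile(rng_seed = 5)
  g <- generate_trial(p5, trial_spec("N", 0.54, duration = 5))
  r1 <- run_reservoir(g, cfg, b, p)
  r2 <- run_reservoir(g, cfg, b, p)
  expect_identical(r1$activations, r2$activations)
})

test_that("energy decay: with drive off node amplitudes fall monotonically", {
  b <- beam_params()
  A <- duffing_settle(beam_force(b), 3000, b)
  amps <- numeric(30)
  for (i in seq_along(amps)) {
    A <- duffing_envelope_step(A, drive = 0, detuning = 3000, b = b)
    amps[i] <- Mod(A)
  }
  expect_true(all(diff(amps) < 0))
  expect_lt(amps[30] / amps[1], 1)
})

test_that("surrogate reservoir contract: shape, rate and fixed point", {
  cfg30 <- multiplex_config(n_nodes = 30, node_separation = 7e-3 / 30)
  tr <- accel_trace(rep(0, 200), 142.85)
  # zero input, zero feedback/coupling -> constant sigmoid(0) = 1/2
  r0 <- surrogate_reservoir(tr, cfg30, input_gain = 1, feedback_gain = 0,
                            coupling = 0)
  expect_equal(as.numeric(r0$activations), rep(0.5, 30 * 200))

  # same output shape and update rate as the physical simulation on the
  # same input and node layout
  p5 <- subject_profile(rng_seed = 5)
  g <- generate_trial(p5, trial_spec("N", 0.54, duration = 5))
  rs <- surrogate_reservoir(g, cfg30)
  rf <- run_reservoir(g, cfg30)
  expect_equal(dim(rs$activations), dim(rf$activations))
  expect_equal(rs$timestep_rate, rf$timestep_rate)
})

test_that("single-step integrator agrees with the multiplexed run", {
  # the R-level step function and the C++ node loop advance the same
  # envelope equation
  b <- beam_params()
  cfg <- multiplex_config(n_nodes = 1, feedback_gain = 0)
  cfg$input_mask <- 1
  p <- proof_mass_params()
  disp <- 2e-7
  st <- multiplex(disp, cfg, b, p, prev_nodes = 0, A0 = 0.3 + 0.1i,
                  substeps = 8)
  F <- beam_force(b) * (1 + cfg$input_gain * disp / p$transduction_gap)
  A <- 0.3 + 0.1i
  for (i in 1:8) {
    A <- duffing_envelope_step(A, F, beam_detuning(b), b,
                               dt = cfg$node_separation / 8)
  }
  expect_equal(st$activations, Mod(A), tolerance = 1e-12)
})
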