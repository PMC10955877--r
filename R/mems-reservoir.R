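#' Proof-mass parameters
#'
#' Physical parameters of the suspended inertial mass whose displacement
#' modulates the electrostatic drive of the computing beam. Defaults match
#' the fabricated device: 49 ug mass, 6.8 N/m spring constant, motion
#' limited to 5 um by stopper structures, 8 um transduction gap.
#'
#' @param mass proof mass (kg).
#' @param spring_constant suspension stiffness (N/m).
#' @param quality_factor dimensionless damping quality factor of the
#'   proof-mass resonance (air-damped device).
#' @param stopper_limit displacement limit (m) imposed by the stoppers.
#' @param transduction_gap electrostatic gap (m) between mass and beam.
#' @return object of class `proof_mass_params`.
#' @export
proof_mass_params <- function(mass = 49e-9, spring_constant = 6.8,
                              quality_factor = 2, stopper_limit = 5e-6,
                              transduction_gap = 8e-6) {
  stopifnot(mass > 0, spring_constant > 0, transduction_gap > 0,
            quality_factor > 0, stopper_limit > 0,
            stopper_limit < transduction_gap)
  structure(list(mass = mass, spring_constant = spring_constant,
                 quality_factor = quality_factor,
                 stopper_limit = stopper_limit,
                 transduction_gap = transduction_gap),
            class = "proof_mass_params")
}

#' Nonlinear-beam (Duffing) parameters
#'
#' Envelope-level description of the doubly clamped silicon beam. The
#' beam's fast (~500 kHz) oscillation is not resolved; its slowly varying
#' complex amplitude A obeys the rotating-frame averaged equation
#' `dA/dt = (i*detuning - 1/tau) A - i*gamma |A|^2 A - i F/2`,
#' where `detuning = 2*pi*(drive_frequency - natural_frequency)` and F is
#' the effective drive force (proportional to the drive voltage). With
#' `gamma > 0` the response peak sits at `detuning = gamma |A|^2`: the
#' resonance leans toward higher frequencies as the drive grows
#' (stiffening).
#'
#' @param decay_time envelope decay time tau (s).
#' @param natural_frequency beam resonance (Hz).
#' @param duffing_coefficient stiffening coefficient gamma
#'   (rad/s per squared envelope unit); nonnegative.
#' @param drive_frequency drive tone frequency (Hz), within the swept band
#'   493.4-501.0 kHz.
#' @param base_drive_amplitude drive voltage amplitude (V), in [30, 109].
#' @param force_per_volt conversion from drive voltage to effective
#'   envelope force (places the operating point on the steep, nonlinear
#'   part of the response at the default 70 V drive).
#' @return object of class `beam_params`.
#' @export
beam_params <- function(decay_time = 150e-6, natural_frequency = 497e3,
                        duffing_coefficient = 8000,
                        drive_frequency = 497.5e3,
                        base_drive_amplitude = 70,
                        force_per_volt = 210) {
  stopifnot(decay_time > 0, duffing_coefficient >= 0,
            drive_frequency >= 493.4e3, drive_frequency <= 501.0e3,
            base_drive_amplitude >= 30, base_drive_amplitude <= 109)
  structure(list(decay_time = decay_time,
                 natural_frequency = natural_frequency,
                 duffing_coefficient = duffing_coefficient,
                 drive_frequency = drive_frequency,
                 base_drive_amplitude = base_drive_amplitude,
                 force_per_volt = force_per_volt),
            class = "beam_params")
}

beam_detuning <- function(b) 2 * pi * (b$drive_frequency - b$natural_frequency)
beam_force <- function(b) b$force_per_volt * b$base_drive_amplitude

#' Time-multiplexing configuration
#'
#' Virtual-node layout: N nodes of separation theta share the single
#' physical beam within each classifier timestep, so that one timestep
#' spans N*theta seconds (7 ms for the defaults, i.e. a 142.857 Hz
#' activation update rate). Each node applies its own mask value to the
#' drive modulation; the previous timestep's activations are fed back into
#' the drive to couple the virtual nodes in time.
#'
#' @param n_nodes number N of virtual nodes.
#' @param node_separation node sampling interval theta (s); must be
#'   shorter than the beam decay time.
#' @param feedback_gain gain of the delayed activation feedback on the
#'   drive amplitude.
#' @param input_gain gain of the gap-modulation input on the drive
#'   amplitude (the normalized gap modulation is of order 1e-2 for ~1 g
#'   accelerations, hence the large default).
#' @param mask_values `"uniform"` for masks drawn uniform[-1, 1] (the
#'   default: per-node gain diversity improves the linear separability of
#'   the activations) or `"binary"` for masks in {-1, +1}.
#' @param rng_seed seed for the mask draw.
#' @return object of class `multiplex_config` with the drawn `input_mask`.
#' @export
multiplex_config <- function(n_nodes = 100, node_separation = 70e-6,
                             feedback_gain = 0.2, input_gain = 60,
                             mask_values = c("uniform", "binary"),
                             rng_seed = 42L) {
  mask_values <- match.arg(mask_values)
  stopifnot(n_nodes >= 1, node_separation > 0)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  mask <- if (mask_values == "binary") {
    sample(c(-1, 1), n_nodes, replace = TRUE)
  } else {
    stats::runif(n_nodes, -1, 1)
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 node_separation = node_separation,
                 input_mask = mask, feedback_gain = feedback_gain,
                 input_gain = input_gain, rng_seed = as.integer(rng_seed)),
            class = "multiplex_config")
}

#' Timestep period and activation update rate of a multiplex layout
#' @param cfg a [multiplex_config()].
#' @return `timestep_period()`: N*theta in seconds. `update_rate()`:
#'   1/(N*theta) in Hz.
#' @export
timestep_period <- function(cfg) cfg$n_nodes * cfg$node_separation

#' @rdname timestep_period
#' @export
update_rate <- function(cfg) 1 / timestep_period(cfg)

#' Proof-mass displacement response
#'
#' Integrates the damped driven oscillator
#' `m x'' + (m w0/Q) x' + k x = -m a(t)` for the proof mass under an
#' external acceleration, with hard clipping of the displacement at the
#' stopper limit. Initial conditions are zero; a 4th-order explicit scheme
#' is used with an integration step no larger than the node separation.
#'
#' @param accel an [accel_trace()] (samples in g) or numeric vector of
#'   accelerations in g.
#' @param p a [proof_mass_params()].
#' @param sample_rate input rate (Hz); taken from the trace if given.
#' @param g0 standard gravity (m/s^2).
#' @return numeric vector of displacements (m) at the input sample times.
#' @export
proof_mass_response <- function(accel, p = proof_mass_params(),
                                sample_rate = NULL, g0 = 9.81) {
  if (inherits(accel, "accel_trace")) {
    sample_rate <- accel$sample_rate
    accel <- accel$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required for numeric input")
  if (!all(is.finite(accel))) stop("non-finite acceleration input")
  dt_in <- 1 / sample_rate
  substeps <- max(1L, ceiling(dt_in / 70e-6))
  cpp_proof_mass(accel * g0, dt_in, substeps, p$mass, p$spring_constant,
                 p$quality_factor, p$stopper_limit)
}

#' Advance the beam envelope by one integration step
#'
#' Single step of the rotating-frame averaged (slow-flow) equation for the
#' beam's complex oscillation amplitude, using the classical 4th-order
#' scheme.
#'
#' @param A complex envelope amplitude.
#' @param drive effective drive force F.
#' @param detuning drive detuning from resonance (rad/s).
#' @param b a [beam_params()] (supplies tau and gamma).
#' @param dt integration step (s); must not exceed a quarter of the node
#'   separation (17.5 us for the default layout).
#' @return new complex amplitude.
#' @export
duffing_envelope_step <- function(A, drive, detuning, b = beam_params(),
                                  dt = 70e-6 / 8) {
  if (dt > 70e-6 / 4 + 1e-12) {
    stop("integration step dt must be <= theta/4 = 17.5 us")
  }
  cpp_duffing_step(as.complex(A), drive, detuning, b$decay_time,
                   b$duffing_coefficient, dt)[1]
}

#' Steady-state envelope amplitude at constant drive
#'
#' Integrates the envelope equation to steady state (20 decay times by
#' default) and returns the final complex amplitude.
#'
#' @inheritParams duffing_envelope_step
#' @param A0 initial amplitude.
#' @param settle_time integration time (s).
#' @return complex amplitude after settling.
#' @export
duffing_settle <- function(drive, detuning, b = beam_params(),
                           A0 = 0 + 0i, settle_time = 20 * b$decay_time,
                           dt = 70e-6 / 8) {
  nsteps <- ceiling(settle_time / dt)
  cpp_duffing_run(as.complex(A0), drive, detuning, b$decay_time,
                  b$duffing_coefficient, dt, nsteps)[1]
}

#' Quasi-static frequency sweep of the beam response
#'
#' Sweeps the drive frequency across a grid (upward or downward),
#' letting the envelope settle at each point while carrying the state
#' over, as in a hardware network-analyzer sweep. With a stiffening
#' nonlinearity and large drive, upward and downward sweeps disagree over
#' a frequency interval (hysteresis) and the response peak moves up in
#' frequency as the drive amplitude grows.
#'
#' @param b a [beam_params()].
#' @param drive_voltage drive amplitude (V).
#' @param freq_grid drive frequencies (Hz) to sweep.
#' @param direction `"up"` or `"down"`.
#' @param settle_time settling time per frequency point (s).
#' @return data.frame with columns `freq` and `amplitude` (in sweep order).
#' @export
duffing_sweep <- function(b = beam_params(),
                          drive_voltage = b$base_drive_amplitude,
                          freq_grid = seq(493.4e3, 501.0e3, by = 400),
                          direction = c("up", "down"),
                          settle_time = 30 * b$decay_time) {
  direction <- match.arg(direction)
  grid <- sort(freq_grid, decreasing = direction == "down")
  F <- b$force_per_volt * drive_voltage
  A <- 0 + 0i
  amp <- numeric(length(grid))
  for (i in seq_along(grid)) {
    det <- 2 * pi * (grid[i] - b$natural_frequency)
    A <- duffing_settle(F, det, b, A0 = A, settle_time = settle_time)
    amp[i] <- Mod(A)
  }
  data.frame(freq = grid, amplitude = amp)
}

#' One timestep of the time-multiplexed beam reservoir
#'
#' For node j of a timestep, the effective drive amplitude over its theta
#' interval is `F0 * (1 + input_gain * mask_j * s + feedback_gain *
#' x(n-1)_j)`, with `s` the normalized gap modulation
#' (displacement / transduction gap) sampled at the node rate. The node
#' activation is the envelope magnitude |A| at the end of the interval;
#' the beam state carries over between nodes without reset.
#'
#' @param displacement displacement samples (m) covering the timestep,
#'   one per node (length `n_nodes`).
#' @param cfg a [multiplex_config()].
#' @param b a [beam_params()].
#' @param p a [proof_mass_params()] (supplies the transduction gap).
#' @param prev_nodes previous timestep's activation vector (length N).
#' @param A0 complex beam state entering the timestep.
#' @param substeps envelope integration substeps per node interval.
#' @return list with `activations` (length-N vector) and `A` (beam state
#'   leaving the timestep).
#' @export
multiplex <- function(displacement, cfg, b = beam_params(),
                      p = proof_mass_params(),
                      prev_nodes = numeric(cfg$n_nodes), A0 = 0 + 0i,
                      substeps = 8) {
  stopifnot(length(displacement) == cfg$n_nodes,
            length(prev_nodes) == cfg$n_nodes)
  s <- displacement / p$transduction_gap
  X <- cpp_multiplex_state(s, cfg$input_mask, cfg$node_separation,
                           as.integer(substeps), b$decay_time,
                           b$duffing_coefficient, beam_detuning(b),
                           beam_force(b), cfg$input_gain,
                           cfg$feedback_gain, prev_nodes,
                           as.complex(A0))
  list(activations = as.numeric(X$activations), A = X$A[1])
}

#' Run the full beam reservoir over an acceleration trace
#'
#' Chains the proof-mass response and the time-multiplexed beam envelope
#' over all timesteps: the displacement is resampled to the node rate
#' 1/theta, split into timesteps of N nodes, and each node interval drives
#' the beam as in [multiplex()]. The number of timesteps is
#' `M = floor(duration / (N * theta))`.
#'
#' @param accel an [accel_trace()] at either supported rate.
#' @param cfg a [multiplex_config()].
#' @param b a [beam_params()].
#' @param p a [proof_mass_params()].
#' @param substeps envelope integration substeps per node interval.
#' @return object of class `reservoir_trace`: `activations` (N x M matrix
#'   of envelope magnitudes) and `timestep_rate` (Hz).
#' @export
run_reservoir <- function(accel, cfg = multiplex_config(),
                          b = beam_params(), p = proof_mass_params(),
                          substeps = 8) {
  stopifnot(inherits(accel, "accel_trace"))
  disp <- proof_mass_response(accel, p)
  duration <- length(accel$samples) / accel$sample_rate
  theta <- cfg$node_separation
  M <- floor(duration / (cfg$n_nodes * theta))
  if (M < 1) stop("trace shorter than one timestep")
  t_in <- (seq_along(disp) - 1) / accel$sample_rate
  t_node <- (seq_len(cfg$n_nodes * M) - 1) * theta
  s <- stats::approx(t_in, disp, xout = t_node, rule = 2)$y /
    p$transduction_gap
  X <- cpp_multiplex(s, cfg$input_mask, theta, as.integer(substeps),
                     b$decay_time, b$duffing_coefficient,
                     beam_detuning(b), beam_force(b), cfg$input_gain,
                     cfg$feedback_gain, numeric(cfg$n_nodes))
  reservoir_trace(X, update_rate(cfg))
}

#' Reservoir activation container
#' @param activations N x M matrix of node activations.
#' @param timestep_rate activation update rate (Hz).
#' @return object of class `reservoir_trace`.
#' @export
reservoir_trace <- function(activations, timestep_rate) {
  stopifnot(is.matrix(activations), all(is.finite(activations)))
  structure(list(activations = activations, timestep_rate = timestep_rate),
            class = "reservoir_trace")
}

#' @export
print.reservoir_trace <- function(x, ...) {
  cat(sprintf("<reservoir_trace> %d nodes x %d timesteps @ %.2f Hz\n",
              nrow(x$activations), ncol(x$activations), x$timestep_rate))
  invisible(x)
}

#' Fast surrogate reservoir
#'
#' Drop-in replacement for [run_reservoir()] that swaps the beam physics
#' for a sigmoidal recurrent map on the same virtual-node layout:
#' `x_j(n) = sigmoid(input_gain * mask_j * s(n) + feedback_gain *
#' x_j(n-1) + coupling * x_{j-1}(n))`, with the acceleration (in g) as the
#' per-timestep input `s(n)`. It produces activations with the same shape
#' and update rate as the physical simulation at a small fraction of the
#' cost, and is the reservoir used in the end-to-end pipeline tests.
#'
#' @param accel an [accel_trace()].
#' @param cfg a [multiplex_config()] (supplies nodes and mask).
#' @param input_gain,feedback_gain,coupling surrogate map gains.
#' @return a `reservoir_trace`.
#' @export
surrogate_reservoir <- function(accel, cfg = multiplex_config(),
                                input_gain = 8, feedback_gain = 0.6,
                                coupling = 2) {
  stopifnot(inherits(accel, "accel_trace"))
  s <- timestep_input(accel, cfg)
  X <- cpp_surrogate(s, cfg$input_mask, input_gain, feedback_gain, coupling)
  reservoir_trace(X, update_rate(cfg))
}

# Per-timestep scalar input: the acceleration resampled at the layout's
# activation update rate (linear interpolation), so the surrogate's
# timestep count matches the physical simulation's for any node layout.
timestep_input <- function(accel, cfg) {
  rate <- accel$sample_rate
  target <- update_rate(cfg)
  if (abs(rate - target) / target < 1e-6) return(accel$samples)
  M <- floor(length(accel$samples) / rate * target)
  t_in <- (seq_along(accel$samples) - 1) / rate
  stats::approx(t_in, accel$samples, xout = (seq_len(M) - 1) / target,
                rule = 2)$y
}
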