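---
title: "Methods: in-sensor reservoir classification of gait patterns"
author: "memsgait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-sensor reservoir classification of gait patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsgait)
```

## The system being modelled

`memsgait` simulates and evaluates a wearable gait classifier in which a
MEMS accelerometer is also the computer. A suspended proof mass (49 µg,
6.8 N/m suspension, motion clipped at ±5 µm by stoppers) senses foot
accelerations; its displacement modulates, across an 8 µm electrostatic
gap, the drive of a doubly clamped silicon beam operated in its
stiffening (Duffing) regime. The beam's oscillation envelope is a fast
(decay time τ = 150 µs) nonlinear function of the drive, and a
time-multiplexing loop turns the single beam into N = 100 *virtual
nodes*: each classifier timestep of N·θ = 7 ms is divided into θ = 70 µs
node intervals, each with its own input mask weight and a delayed
feedback of the previous timestep's activations. Sampling the envelope
at the end of each interval yields a 100-dimensional activation vector
at 142.857 Hz.

Only a linear readout is trained. Activations are leaky-integrated,

$$x(n) = (1-\alpha)\,x(n-1) + \alpha\,\tilde{x}(n),$$

collected (after discarding a 1000-timestep transient) into a matrix
$X \in \mathbb{R}^{(1+N)\times M}$ with a bias row of ones, and mapped to
a two-row one-hot target $Y$ (TO and TL indicator channels; the four
gait classes are N = (0,0), TO = (1,0), TL = (0,1), TOTL = (1,1)) by
ridge regression,

$$W_\mathrm{out} = Y X^\top (X X^\top + \beta I)^{-1}.$$

At inference the two raw channels $y(n) = W_\mathrm{out}\bar{x}(n)$ are
smoothed by a causal 300-timestep moving average (≈2.1 s, matching the
gait timescale) and thresholded; each channel's threshold is chosen on
training data to minimise |TPR − TNR|. Two reference classifiers share
the protocol: a leaky-integrator echo state network with the same node
count, and a windowed logistic regression on the filtered acceleration
(71.5 Hz FIR, 715-sample windows downsampled by 2 plus the window mean —
359 features — standardised with training-fold statistics, two
independent L2 fits with C = 1).

## The synthetic gait generator

No public accession is printed for the human recordings, so the package
generates cohorts with the protocol's shape: 10 subjects, 4 gait
patterns (normal, toe-out, trunk-lean, combined), 5 belt speeds
(0.36–0.72 m/s), 90 s sequences sampled at 14285 Hz or directly at the
142.85 Hz timestep rate. A subject's normal-gait acceleration is

* a harmonic series at the step frequency (four harmonics, ≈0.55 g
  fundamental at the 0.54 m/s reference), giving the 0.5–15 Hz
  low-frequency content and ~1 g amplitude of foot-worn recordings;
* a heel-strike transient per cycle: a Gaussian-windowed chirp centred
  near 35 Hz (width 20 ms, 15 Hz chirp span) with per-cycle timing and
  amplitude jitter;
* white measurement noise (σ = 0.02 g).

Step frequency scales with belt speed as $\sqrt{v/0.54}$ (the constant
walk-ratio assumption) and amplitudes as $(v/0.54)^{0.7}$; both are
standard biomechanical scalings, fixed once — no cadence measurements
are available to fit. Subject individuality enters as lognormal jitter of the
step frequency (CV 8%), harmonic amplitudes (15%), transient parameters
(15–20%) and normal jitter of harmonic phases (0.1 rad).

### How the patterns are encoded, and why

The class structure is the load-bearing design choice. On foot-worn
hardware recordings, trunk-lean is *demonstrably* invisible to linear
classifiers while nonlinear ones read it well — an empirical fact
without a published mechanistic explanation — so the generator
reproduces that ordering **by construction**:

* **Toe-out** rotates the foot outward, changing the gravity projection
  on the sensing axis (+0.08 g DC) and boosting the even step harmonics
  (×1.5, +0.6 rad). These are first- and second-order signatures — a
  linear model at fixed speed can see them.
* **Trunk-lean** changes no per-frequency power at all. It flips the
  even-harmonic phases by π, reversing the waveform's triad phase
  closures (the third moment $\overline{s^3}$ changes sign), and
  time-reverses the heel-strike chirp (up-chirp → down-chirp). Both are
  phase-only edits: the magnitude spectrum — hence every second-order
  statistic of a randomly-phased window — is unchanged, so *no linear
  functional of the raw window* separates TL from N. A classifier must
  form nonlinear (third-order or cross-time) statistics, which is
  exactly what reservoir activations feed to a linear readout.
* **TOTL** composes both edits.

Because `generate_trial()` draws all randomness before pattern effects
are applied, two trials differing only in the pattern share their noise
and jitter: the pattern acts as a controlled intervention, which is what
makes the spectrum-match property testable at all.

The spectral match is asserted on smoothed, tapered periodograms over
the bins that jointly carry 90% of the N-trial power (measured
difference ≈3%, bound 5%). A finite record makes an all-bins bound
meaningless: between harmonic lines, leakage-skirt interference flips
sign under any phase edit, producing order-one *relative* differences at
bins holding ~10⁻⁴ of the peak power. The heel-strike transient is
Gaussian-windowed precisely so that its energy stays out of the harmonic
band and cannot leak the phase flip into magnitudes there.

The generator emulates the amplitude, band, timing and class geometry of
foot-worn gait recordings. It does **not** emulate non-stationary gait
drift, stride-to-stride waveform variability beyond parameter jitter,
3-D kinematics, or the actual biomechanics of toe-out and trunk-lean —
the pattern encodings are stand-ins whose only obligation is the
classifier ordering. Passing tests therefore validate the pipeline's
machinery, not clinical performance on real subjects.

## Reservoir simulation choices

The beam is simulated at the envelope level: the complex amplitude obeys
the rotating-frame slow-flow equation

$$\dot A = (i\delta - 1/\tau) A + i\gamma |A|^2 A - iF/2,$$

advanced by a classical 4th-order scheme with step θ/8. This skips the
~500 kHz carrier (three orders of magnitude faster) while retaining the
observable the hardware digitises — the envelope. The integrator is
validated against closed forms: free decay $e^{-t/\tau}$, and the
γ = 0 Lorentzian fixed point $|A| = (F/2)\tau/\sqrt{1+(\delta\tau)^2}$
(matched to 10⁻⁴ over a 20-point detuning grid). With γ > 0 swept
responses lean toward higher frequencies as drive grows and up/down
sweeps disagree over an interval (hysteresis), as in the hardware
characterisation.

The electrostatic drive is linearised in the gap modulation
(F ∝ 1 + s, s = displacement/gap), keeping one input gain and leaving
the nonlinearity where the device has it — the beam. The feedback loop
is the standard delay-reservoir scheme (per-node self-feedback of the
previous timestep); the hardware's exact wiring is not public, so all
gains are configuration, and no hardware fidelity is claimed. The
operating point (γ = 3000 rad/s per unit |A|², δ/2π = 500 Hz, 70 V drive
scaled to F with 210 force-units/V) places the beam on the steep flank
of its nonlinear response at |A| ≈ 1.

`surrogate_reservoir()` swaps the physics for a sigmoidal recurrent map
on the same node layout (input masks, self-feedback, nearest-node
coupling) at ~100× the speed, and is the reservoir used by the
end-to-end tests and the acceptance analysis. Its gains
(input 8, feedback 0.6, coupling 2) and the readout defaults
(α = 0.02, β = 10⁻²) were calibrated once, with the
`readout_grid_search()` helper on a seeded fixed-speed cohort, to place
the nodes well into their nonlinear regime; masks are drawn
uniform[−1, 1] because with a scalar input per timestep, binary masks
collapse the node set to two distinct responses and measurably weaken
the readout.

## Evaluation protocol

Each recording is split into four **contiguous** folds (remainder
samples to the last fold); split *s* trains on the other three folds of
every recording in the condition and tests on fold *s*, so each
timestep is tested exactly once. Contiguity is deliberate time-series
hygiene: shuffled folds would leak across the 300-step moving average,
which is restarted at every fold boundary for the same reason. Feature
standardisation (LR) and threshold selection use training folds only —
a mutation test that leaks global statistics verifies the isolation
changes results. Reported AUCs are means over the four splits, computed
per condition with recordings pooled (a recording has a single
prescribed pattern, so ROC needs the pooled folds); the alternative —
averaging AUCs computed per recording — is not meaningful here for the
same reason. Box summaries use linear-interpolation quartiles and
1.5×IQR whiskers.

Numerical conventions worth stating: the leaky integrator starts at the
first sample (no startup bias); threshold candidates are midpoints of
consecutive distinct scores with ties broken toward the larger
threshold; ROC ties enter simultaneously and the AUC is trapezoidal
(equal to Mann–Whitney pair counting with half-weight ties, verified
exhaustively at small n); the ridge system reports rank deficiency at
β = 0 rather than silently pseudo-inverting.

## Problem sizes

The package's own analyses (tests and the acceptance script) use a
10-subject cohort at the fixed 0.54 m/s speed with 60 s trials and the
surrogate reservoir — about 343k classifier timesteps — which keeps the
full three-classifier comparison to minutes on one core while leaving
the protocol itself (transient, folds, smoothing, thresholds) at the
device's true rates. Full-physics reservoir runs and raw-rate
(14285 Hz) traces are exercised on shorter trials where the physics,
not the cohort statistics, is under test.

## Known limitations

* The pattern encodings are constructions, not biomechanics; only the
  qualitative classifier ordering (reservoir ≈ ESN ≫ linear on TL) is
  expected to transfer to real data.
* The beam model is envelope-level with a single cubic coefficient;
  thermal noise, higher modes and circuit non-idealities are out of
  scope (an optional front-end distortion filter emulates the
  sensitivity curve only).
* ESN and surrogate hyperparameters are calibrated defaults, not the
  (unpublished) hardware values.
* With a shared scalar input per timestep the surrogate's nodes are
  less diverse than hardware virtual nodes, which see the input at
  different sub-timestep phases.
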