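#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- Proof-mass inertial dynamics -----------------------------------------
// m x'' + (m w0 / Q) x' + k x = -m a(t), hard position clipping at the
// stopper limit. RK4 with linear interpolation of a(t) between input
// samples; `substeps` integration steps per input sample.

static inline double interp_a(const NumericVector& a, double idx) {
  int i = (int)std::floor(idx);
  int n = a.size();
  if (i >= n - 1) return a[n - 1];
  double w = idx - i;
  return a[i] * (1.0 - w) + a[i + 1] * w;
}

// [[Rcpp::export]]
NumericVector cpp_proof_mass(NumericVector accel_ms2, double dt_in,
                             int substeps, double mass, double spring_k,
                             double Q, double limit) {
  int n = accel_ms2.size();
  double w0 = std::sqrt(spring_k / mass);
  double c = w0 / Q;               // damping rate
  double k_m = spring_k / mass;
  double dt = dt_in / substeps;
  NumericVector out(n);
  double x = 0.0, v = 0.0;
  out[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    for (int s = 0; s < substeps; ++s) {
      double t0 = (i - 1) + (double)s / substeps;      // in input-sample units
      auto acc = [&](double tt) { return interp_a(accel_ms2, tt); };
      double a1 = acc(t0), a2 = acc(t0 + 0.5 / substeps),
             a4 = acc(t0 + 1.0 / substeps);
      // RK4 on (x, v)
      double k1x = v;
      double k1v = -c * v - k_m * x - a1;
      double x2 = x + 0.5 * dt * k1x, v2 = v + 0.5 * dt * k1v;
      double k2x = v2, k2v = -c * v2 - k_m * x2 - a2;
      double x3 = x + 0.5 * dt * k2x, v3 = v + 0.5 * dt * k2v;
      double k3x = v3, k3v = -c * v3 - k_m * x3 - a2;
      double x4 = x + dt * k3x, v4 = v + dt * k3v;
      double k4x = v4, k4v = -c * v4 - k_m * x4 - a4;
      x += dt / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
      v += dt / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
      if (x > limit)  { x = limit;  if (v > 0) v = 0; }
      if (x < -limit) { x = -limit; if (v < 0) v = 0; }
    }
    out[i] = x;
  }
  return out;
}

// ---- Duffing-beam envelope (slow flow) ------------------------------------
// dA/dt = (i*detuning - 1/tau) A - i*gamma*|A|^2 A - i*F/2
// gamma >= 0 is stiffening: the response peak sits at
// detuning = gamma*|A|^2 > 0, i.e. it moves up in frequency with drive.
// Classical RK4 on the complex amplitude.

static inline std::complex<double> duff_rhs(std::complex<double> A,
                                            double F, double detuning,
                                            double tau, double gamma) {
  std::complex<double> i(0.0, 1.0);
  double A2 = std::norm(A);
  return (i * detuning - 1.0 / tau) * A - i * gamma * A2 * A - i * F / 2.0;
}

static inline std::complex<double> duff_step(std::complex<double> A,
                                             double F, double detuning,
                                             double tau, double gamma,
                                             double dt) {
  std::complex<double> k1 = duff_rhs(A, F, detuning, tau, gamma);
  std::complex<double> k2 = duff_rhs(A + 0.5 * dt * k1, F, detuning, tau, gamma);
  std::complex<double> k3 = duff_rhs(A + 0.5 * dt * k2, F, detuning, tau, gamma);
  std::complex<double> k4 = duff_rhs(A + dt * k3, F, detuning, tau, gamma);
  return A + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

// [[Rcpp::export]]
ComplexVector cpp_duffing_step(ComplexVector A0, double F, double detuning,
                               double tau, double gamma, double dt) {
  std::complex<double> A(A0[0].r, A0[0].i);
  A = duff_step(A, F, detuning, tau, gamma, dt);
  if (!std::isfinite(A.real()) || !std::isfinite(A.imag()) ||
      std::abs(A) > 1e9) {
    stop("beam envelope diverged (|A| overflow): F=%g detuning=%g gamma=%g",
         F, detuning, gamma);
  }
  ComplexVector out(1);
  out[0].r = A.real(); out[0].i = A.imag();
  return out;
}

// Integrate the envelope for nsteps at constant drive; returns final A.
// [[Rcpp::export]]
ComplexVector cpp_duffing_run(ComplexVector A0, double F, double detuning,
                              double tau, double gamma, double dt,
                              int nsteps) {
  std::complex<double> A(A0[0].r, A0[0].i);
  for (int s = 0; s < nsteps; ++s) {
    A = duff_step(A, F, detuning, tau, gamma, dt);
    if (!std::isfinite(A.real()) || !std::isfinite(A.imag()) ||
        std::abs(A) > 1e9) {
      stop("beam envelope diverged (|A| overflow): F=%g detuning=%g gamma=%g",
           F, detuning, gamma);
    }
  }
  ComplexVector out(1);
  out[0].r = A.real(); out[0].i = A.imag();
  return out;
}

// ---- Time-multiplexed virtual nodes ---------------------------------------
// s: gap-modulation samples at the node rate (length N*M); node j of
// timestep n sees constant drive F0*(1 + input_gain*mask_j*s +
// feedback_gain*xprev_j) over its theta interval; |A| is sampled at the
// end of the interval; beam state carries over with no reset.

// [[Rcpp::export]]
NumericMatrix cpp_multiplex(NumericVector s, NumericVector mask,
                            double theta, int substeps, double tau,
                            double gamma, double detuning, double F0,
                            double input_gain, double feedback_gain,
                            NumericVector prev0) {
  int N = mask.size();
  int M = s.size() / N;
  NumericMatrix X(N, M);
  NumericVector prev = clone(prev0);
  std::complex<double> A(0.0, 0.0);
  double dt = theta / substeps;
  for (int n = 0; n < M; ++n) {
    for (int j = 0; j < N; ++j) {
      double sj = s[n * N + j];
      if (std::abs(sj) >= 1.0)
        stop("gap modulation |s| >= 1 at timestep %d node %d (pull-in)",
             n + 1, j + 1);
      double F = F0 * (1.0 + input_gain * mask[j] * sj +
                       feedback_gain * prev[j]);
      for (int ss = 0; ss < substeps; ++ss)
        A = duff_step(A, F, detuning, tau, gamma, dt);
      if (!std::isfinite(A.real()) || !std::isfinite(A.imag()) ||
          std::abs(A) > 1e9)
        stop("beam envelope diverged at timestep %d node %d", n + 1, j + 1);
      X(j, n) = std::abs(A);
    }
    for (int j = 0; j < N; ++j) prev[j] = X(j, n);
  }
  return X;
}

// Single timestep with explicit beam state in/out (used by multiplex()).
// [[Rcpp::export]]
List cpp_multiplex_state(NumericVector s, NumericVector mask, double theta,
                         int substeps, double tau, double gamma,
                         double detuning, double F0, double input_gain,
                         double feedback_gain, NumericVector prev,
                         ComplexVector A0) {
  int N = mask.size();
  NumericVector act(N);
  std::complex<double> A(A0[0].r, A0[0].i);
  double dt = theta / substeps;
  for (int j = 0; j < N; ++j) {
    double sj = s[j];
    if (std::abs(sj) >= 1.0)
      stop("gap modulation |s| >= 1 at node %d (pull-in)", j + 1);
    double F = F0 * (1.0 + input_gain * mask[j] * sj +
                     feedback_gain * prev[j]);
    for (int ss = 0; ss < substeps; ++ss)
      A = duff_step(A, F, detuning, tau, gamma, dt);
    if (!std::isfinite(A.real()) || !std::isfinite(A.imag()) ||
        std::abs(A) > 1e9)
      stop("beam envelope diverged at node %d", j + 1);
    act[j] = std::abs(A);
  }
  ComplexVector Aout(1);
  Aout[0].r = A.real(); Aout[0].i = A.imag();
  return List::create(Named("activations") = act, Named("A") = Aout);
}

// ---- Surrogate reservoir ---------------------------------------------------
// x_j(n) = sigmoid(input_gain*mask_j*s(n) + feedback_gain*x_j(n-1)
//                  + coupling*x_{j-1}(n)); node 1 couples to node N of the
// previous timestep (delay-line topology).

// [[Rcpp::export]]
NumericMatrix cpp_surrogate(NumericVector s, NumericVector mask,
                            double input_gain, double feedback_gain,
                            double coupling) {
  int N = mask.size(), M = s.size();
  NumericMatrix X(N, M);
  std::vector<double> prev(N, 0.0);
  for (int n = 0; n < M; ++n) {
    for (int j = 0; j < N; ++j) {
      double lat = (j == 0) ? prev[N - 1] : X(j - 1, n);
      double z = input_gain * mask[j] * s[n] + feedback_gain * prev[j] +
                 coupling * lat;
      X(j, n) = 1.0 / (1.0 + std::exp(-z));
    }
    for (int j = 0; j < N; ++j) prev[j] = X(j, n);
  }
  return X;
}

// ---- Echo state network ----------------------------------------------------
// x~ = tanh(W_in [1; u(n)] + W_r x(n-1)); x(n) = (1-a) x(n-1) + a x~

// [[Rcpp::export]]
arma::mat cpp_esn(const arma::vec& u, const arma::mat& Win,
                  const arma::mat& Wr, double alpha, const arma::vec& x0) {
  int M = u.n_elem, N = Win.n_rows;
  arma::mat X(N, M);
  arma::vec x = x0;
  for (int n = 0; n < M; ++n) {
    arma::vec z = Win.col(0) + Win.col(1) * u[n] + Wr * x;
    arma::vec xt = arma::tanh(z);
    x = (1.0 - alpha) * x + alpha * xt;
    X.col(n) = x;
  }
  return X;
}

// ---- Leaky integrator of the readout ---------------------------------------
// x(n) = (1-a) x(n-1) + a x~(n), initialised at the first sample.

// [[Rcpp::export]]
NumericMatrix cpp_leaky(NumericMatrix Xt, double alpha) {
  int N = Xt.nrow(), M = Xt.ncol();
  NumericMatrix X(N, M);
  for (int j = 0; j < N; ++j) X(j, 0) = Xt(j, 0);
  for (int n = 1; n < M; ++n)
    for (int j = 0; j < N; ++j)
      X(j, n) = (1.0 - alpha) * X(j, n - 1) + alpha * Xt(j, n);
  return X;
}
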