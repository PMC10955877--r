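#' Echo-state-network hyperparameters
#'
#' Reference software classifier: a leaky-integrator ESN driven by the
#' single-channel reference acceleration, with the same number of
#' reservoir nodes as the MEMS device has virtual activations. Weight
#' entries are drawn uniform on [-1, 1], sparsified by zeroing entries
#' with probability `sparsity_probability`, then scaled (input/bias
#' scalings for W_in, exact spectral-radius rescale for W_r).
#'
#' @param n_nodes reservoir size N.
#' @param leak leaking rate alpha in (0, 1].
#' @param input_scaling,bias_scaling scalings of the input and bias
#'   columns of W_in.
#' @param spectral_radius target largest |eigenvalue| of W_r.
#' @param sparsity_probability probability of zeroing a weight entry.
#' @param rng_seed seed for the weight draw.
#' @return object of class `esn_params`.
#' @export
esn_params <- function(n_nodes = 100, leak = 0.3, input_scaling = 1.0,
                       bias_scaling = 0.2, spectral_radius = 0.9,
                       sparsity_probability = 0.9, rng_seed = 7L) {
  stopifnot(n_nodes >= 1, leak > 0, leak <= 1, spectral_radius > 0,
            sparsity_probability >= 0, sparsity_probability < 1)
  structure(list(n_nodes = as.integer(n_nodes), leak = leak,
                 input_scaling = input_scaling, bias_scaling = bias_scaling,
                 spectral_radius = spectral_radius,
                 sparsity_probability = sparsity_probability,
                 rng_seed = as.integer(rng_seed)),
            class = "esn_params")
}

#' Initialize ESN weight matrices
#'
#' Weight pipeline order is draw -> sparsify -> scale. The reservoir
#' matrix is rescaled post hoc so its spectral radius matches the target
#' exactly.
#'
#' @param params an [esn_params()].
#' @return object of class `esn_weights`: `W_in` (N x 2, bias column then
#'   input column) and `W_r` (N x N).
#' @export
esn_init_weights <- function(params = esn_params()) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$rng_seed)
  N <- params$n_nodes
  W_in <- matrix(stats::runif(2 * N, -1, 1), N, 2)
  W_r <- matrix(stats::runif(N * N, -1, 1), N, N)
  W_in[matrix(stats::runif(2 * N) < params$sparsity_probability, N, 2)] <- 0
  W_r[matrix(stats::runif(N * N) < params$sparsity_probability, N, N)] <- 0
  W_in[, 1] <- W_in[, 1] * params$bias_scaling
  W_in[, 2] <- W_in[, 2] * params$input_scaling
  rho <- max(Mod(eigen(W_r, only.values = TRUE)$values))
  if (rho == 0) stop("sparsified reservoir matrix is nilpotent-zero; ",
                     "lower sparsity_probability or change the seed")
  W_r <- W_r * (params$spectral_radius / rho)
  structure(list(W_in = W_in, W_r = W_r), class = "esn_weights")
}

#' One ESN state update
#'
#' `xt = tanh(W_in [1; u(n)] + W_r x(n-1))`;
#' `x(n) = (1 - alpha) x(n-1) + alpha xt`.
#'
#' @param u scalar input sample.
#' @param x_prev state vector (length N).
#' @param w an [esn_init_weights()] result.
#' @param leak leaking rate alpha.
#' @return new state vector.
#' @export
esn_step <- function(u, x_prev, w, leak) {
  if (!is.finite(u)) stop("non-finite ESN input")
  xt <- tanh(as.numeric(w$W_in %*% c(1, u) + w$W_r %*% x_prev))
  (1 - leak) * x_prev + leak * xt
}

#' Run the ESN over an input sequence
#'
#' @param u numeric input sequence (acceleration, g).
#' @param params an [esn_params()].
#' @param w optional pre-drawn [esn_init_weights()].
#' @return N x M matrix of states.
#' @export
esn_run <- function(u, params = esn_params(), w = esn_init_weights(params)) {
  if (!all(is.finite(u))) stop("non-finite ESN input")
  cpp_esn(u, w$W_in, w$W_r, params$leak, numeric(params$n_nodes))
}

#' ESN feature matrix for the ridge readout
#'
#' Discards the initial transient and stacks a row of ones and the raw
#' input over the reservoir states, giving a (2+N) x M matrix.
#'
#' @inheritParams esn_run
#' @param transient initial timesteps to discard.
#' @return (2+N) x M numeric matrix: rows are bias, input, then states.
#' @export
esn_features <- function(u, params = esn_params(),
                         w = esn_init_weights(params), transient = 1000L) {
  if (length(u) < transient + 1L) {
    stop("input too short: need more than ", transient, " samples")
  }
  X <- esn_run(u, params, w)
  keep <- (transient + 1L):length(u)
  rbind(rep(1, length(keep)), u[keep], X[, keep, drop = FALSE])
}

#' Logistic-regression pipeline parameters
#'
#' The windowed linear reference classifier: the acceleration is low-pass
#' filtered (Hamming-window FIR), and at each timestep the last
#' `window_len` samples (5 s at the 142.85 Hz timestep rate) are
#' downsampled by 2 and used, together with their mean, as features of two
#' independent L2-regularized logistic models (one per output channel).
#'
#' @param fir_cutoff FIR cutoff frequency (Hz).
#' @param fir_order FIR order (order 40 gives 41 symmetric taps).
#' @param window_len feature window length in samples.
#' @param downsample_factor keep every `downsample_factor`-th sample,
#'   anchored at the most recent one.
#' @param C inverse regularization strength of the logistic fit.
#' @param max_iterations solver iteration cap.
#' @return object of class `lr_params`.
#' @export
lr_params <- function(fir_cutoff = 71.5, fir_order = 40L,
                      window_len = 715L, downsample_factor = 2L,
                      C = 1.0, max_iterations = 100L) {
  stopifnot(fir_cutoff > 0, fir_order >= 2, window_len >= 1,
            downsample_factor >= 1, C > 0)
  structure(list(fir_cutoff = fir_cutoff, fir_order = as.integer(fir_order),
                 window_len = as.integer(window_len),
                 downsample_factor = as.integer(downsample_factor),
                 C = C, max_iterations = as.integer(max_iterations)),
            class = "lr_params")
}

#' Hamming-window FIR low-pass taps
#'
#' Linear-phase windowed-sinc design; `order` gives `order + 1` symmetric
#' taps (group delay `order/2` samples). The normalized cutoff is clamped
#' just below Nyquist when the requested cutoff reaches it.
#'
#' @param cutoff cutoff frequency (Hz).
#' @param sample_rate signal sampling rate (Hz).
#' @param order filter order.
#' @return numeric vector of `order + 1` taps.
#' @export
fir_lowpass <- function(cutoff, sample_rate, order = 40L) {
  wc <- min(cutoff / (sample_rate / 2), 0.999)
  h <- as.numeric(signal::fir1(order, wc, type = "low",
                               window = signal::hamming(order + 1)))
  h / sum(h)    # unit DC gain
}

#' Filter an acceleration sequence for the LR pipeline
#'
#' Applies the FIR low-pass with group-delay compensation (the symmetric
#' taps delay the signal by `order/2` samples; the output is shifted back
#' and edge samples are held).
#'
#' @param u numeric acceleration sequence.
#' @param sample_rate sampling rate (Hz).
#' @param p an [lr_params()].
#' @return filtered sequence, same length as `u`.
#' @export
lr_filter <- function(u, sample_rate = 142.85, p = lr_params()) {
  h <- fir_lowpass(p$fir_cutoff, sample_rate, p$fir_order)
  gd <- p$fir_order / 2
  pad <- c(rep(u[1], gd), u, rep(u[length(u)], gd))
  y <- stats::filter(pad, h, method = "convolution", sides = 1)
  as.numeric(y[(2 * gd + 1):(2 * gd + length(u))])
}

#' LR feature vector at one timestep
#'
#' Features at timestep `n` are every `downsample_factor`-th of the last
#' `window_len` filtered samples, anchored at the most recent sample
#' (indices n - 714, n - 712, ..., n for the defaults: 358 values), plus
#' the mean of the full window: 359 features.
#'
#' @param u filtered acceleration sequence.
#' @param n timestep (1-based index into `u`); must be >= `window_len`.
#' @param p an [lr_params()].
#' @return numeric feature vector of length
#'   `ceiling(window_len / downsample_factor) + 1`.
#' @export
lr_features <- function(u, n, p = lr_params()) {
  if (n < p$window_len) {
    stop("timestep n = ", n, " precedes a full window (", p$window_len, ")")
  }
  idx <- seq(n - p$window_len + 1L, n, by = p$downsample_factor)
  # anchor the subsampling at the most recent sample
  idx <- idx + (n - idx[length(idx)])
  c(u[idx], mean(u[(n - p$window_len + 1L):n]))
}

#' LR feature matrix over a recording
#'
#' Column `m` holds the [lr_features()] vector for timestep
#' `transient + m` of the filtered sequence, so the feature stream is
#' aligned with the transient-trimmed MEMS and ESN feature matrices.
#'
#' @param u raw acceleration sequence at the timestep rate.
#' @param sample_rate sampling rate (Hz).
#' @param p an [lr_params()].
#' @param transient initial timesteps to discard.
#' @return F x M matrix (F = 359 for the defaults).
#' @export
lr_feature_matrix <- function(u, sample_rate = 142.85, p = lr_params(),
                              transient = 1000L) {
  if (length(u) < transient + 1L) {
    stop("input too short: need more than ", transient, " samples")
  }
  lr_window_matrix(lr_filter(u, sample_rate, p), p, transient)
}

#' @rdname lr_feature_matrix
#' @param uf an already-filtered acceleration sequence (see [lr_filter()]).
#' @export
lr_window_matrix <- function(uf, p = lr_params(), transient = 1000L) {
  stopifnot(transient >= p$window_len)
  steps <- (transient + 1L):length(uf)
  nsub <- ceiling(p$window_len / p$downsample_factor)
  off <- rev(seq(0L, by = -p$downsample_factor, length.out = nsub))
  W <- matrix(uf[outer(off, steps, `+`)], nrow = nsub)
  cs <- c(0, cumsum(uf))
  win_means <- (cs[steps + 1L] - cs[steps + 1L - p$window_len]) / p$window_len
  rbind(W, win_means)
}

#' Fit the two-channel L2-regularized logistic classifier
#'
#' Independent binomial fits for the TO and TL channels on standardized
#' features. The optimizer is glmnet's coordinate descent at the single
#' penalty `lambda = 1 / (n * C)` (the L2-logistic maximum a posteriori
#' estimate with inverse regularization `C`, intercept unpenalized).
#' Standardization statistics must come from training data only.
#'
#' @param features F x M matrix of training features (columns are
#'   timesteps).
#' @param Y 2 x M binary target matrix (rows TO, TL).
#' @param p an [lr_params()].
#' @return object of class `lr_model` with the per-channel fits and the
#'   feature standardization statistics.
#' @export
lr_fit <- function(features, Y, p = lr_params()) {
  stopifnot(is.matrix(features), ncol(features) == ncol(Y))
  ctr <- rowMeans(features)
  scl <- apply(features, 1, stats::sd)
  scl[scl == 0] <- 1
  Xs <- t(features)
  Xs <- sweep(Xs, 2L, ctr)
  Xs <- sweep(Xs, 2L, scl, "/")
  n <- nrow(Xs)
  lam <- 1 / (n * p$C)
  fits <- lapply(1:2, function(ch) {
    y <- Y[ch, ]
    if (length(unique(y)) == 1L) {
      # degenerate channel (single class): constant base-rate predictor
      return(structure(list(p = mean(y)), class = "lr_const"))
    }
    # warm-started penalty path down to the target lambda (much faster
    # than a cold single-lambda fit on the highly collinear windows)
    glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                   lambda = lam * 10^seq(3, 0, by = -1),
                   standardize = FALSE, thresh = 1e-8,
                   maxit = max(p$max_iterations * 1000L, 1e5))
  })
  structure(list(fits = fits, center = ctr, scale = scl, params = p,
                 lambda = lam),
            class = "lr_model")
}

#' Predict channel probabilities from an [lr_fit()] model
#'
#' @param model an `lr_model`.
#' @param features F x M feature matrix.
#' @return 2 x M matrix of class probabilities (rows TO, TL).
#' @export
lr_predict <- function(model, features) {
  Xs <- t((features - model$center) / model$scale)
  Y <- vapply(1:2, function(ch) {
    f <- model$fits[[ch]]
    if (inherits(f, "lr_const")) return(rep(f$p, nrow(Xs)))
    as.numeric(stats::predict(f, newx = Xs, s = model$lambda,
                              type = "response"))
  }, numeric(nrow(Xs)))
  t(Y)
}
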