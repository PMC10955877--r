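#' Leaky integration of node activations
#'
#' First-order low-pass recursion applied elementwise to the stream of
#' digitized node samples: `x(n) = (1 - alpha) x(n-1) + alpha xt(n)`,
#' with `x` initialized at the first sample. The leaking rate alpha sets
#' the memory depth of the integrated activations.
#'
#' @param xt numeric matrix (nodes x timesteps) or vector of raw samples.
#' @param alpha leaking rate in (0, 1].
#' @return integrated activations, same shape as `xt`.
#' @export
leaky_integrate <- function(xt, alpha) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1)) {
    stop("alpha must be a scalar in (0, 1]")
  }
  vec <- is.null(dim(xt))
  if (vec) xt <- matrix(xt, nrow = 1)
  out <- cpp_leaky(xt, alpha)
  if (vec) as.numeric(out) else out
}

#' Assemble the training activation matrix
#'
#' Stacks a bias row of ones over the leaky-integrated activations and
#' discards the initial transient, yielding the (1+N) x M matrix used by
#' the ridge readout.
#'
#' @param res a `reservoir_trace` (see [run_reservoir()]) or an N x M
#'   activation matrix.
#' @param alpha leaking rate for [leaky_integrate()].
#' @param transient number of initial timesteps to discard.
#' @return (1+N) x M numeric matrix, row 1 identically 1.
#' @export
activation_matrix <- function(res, alpha = 0.02, transient = 1000L) {
  A <- if (inherits(res, "reservoir_trace")) res$activations else res
  stopifnot(is.matrix(A))
  if (ncol(A) <= transient) {
    stop("need more than ", transient, " timesteps (got ", ncol(A), ")")
  }
  X <- leaky_integrate(A, alpha)
  X <- X[, (transient + 1L):ncol(X), drop = FALSE]
  rbind(rep(1, ncol(X)), X)
}

#' One-hot target matrix for a label stream
#'
#' @param labels per-timestep gait pattern codes (length M).
#' @return 2 x M binary matrix; row 1 is the TO indicator, row 2 the TL
#'   indicator.
#' @export
target_matrix <- function(labels) pattern_to_onehot(labels)

#' Ridge-regression readout training
#'
#' Closed-form L2-regularized least squares for the output weights:
#' `W_out = Y X^T (X X^T + beta I)^{-1}`, with I the identity of the
#' feature dimension.
#'
#' @param X feature matrix (features x timesteps), bias row included.
#' @param Y target matrix (outputs x timesteps).
#' @param beta ridge regularization parameter (>= 0).
#' @return weight matrix W_out (outputs x features).
#' @export
ridge_train <- function(X, Y, beta = 0) {
  stopifnot(is.matrix(X), ncol(X) == ncol(Y), beta >= 0)
  G <- tcrossprod(X) + diag(beta, nrow(X))
  W <- tryCatch(
    t(solve(G, tcrossprod(X, Y))),
    error = function(e) {
      stop("ridge system is rank deficient (X X^T + beta I singular, ",
           "beta = ", beta, "); increase beta", call. = FALSE)
    }
  )
  dimnames(W) <- list(rownames(Y), NULL)
  W
}

#' Trained readout model
#'
#' @param W_out 2 x (1+N) output weight matrix.
#' @param alpha leaking rate used to build activations.
#' @param beta ridge parameter used in training.
#' @param avg_window moving-average window (timesteps).
#' @param thresholds named numeric of detection thresholds (TO, TL).
#' @return object of class `readout_model`.
#' @export
readout_model <- function(W_out, alpha = 0.02, beta = 0, avg_window = 300L,
                          thresholds = c(TO = NA_real_, TL = NA_real_)) {
  stopifnot(is.matrix(W_out), avg_window >= 1, alpha > 0, alpha <= 1,
            beta >= 0)
  structure(list(W_out = W_out, alpha = alpha, beta = beta,
                 avg_window = as.integer(avg_window),
                 thresholds = thresholds),
            class = "readout_model")
}

#' Readout inference
#'
#' Raw two-channel classification signal: `y(n) = W_out xbar(n)` with
#' `xbar(n)` the bias-augmented activation vector (the columns of the
#' activation matrix).
#'
#' @param X activation matrix ((1+N) x M, bias row included).
#' @param model a [readout_model()] or a bare weight matrix.
#' @return 2 x M matrix of raw channel outputs (rows TO, TL).
#' @export
readout_infer <- function(X, model) {
  W <- if (inherits(model, "readout_model")) model$W_out else model
  if (ncol(W) != nrow(X)) {
    stop("shape mismatch: W_out has ", ncol(W), " columns but X has ",
         nrow(X), " rows")
  }
  Y <- W %*% X
  rownames(Y) <- rownames(W)
  Y
}

#' Causal moving average
#'
#' Mean of the last `window` values at each position; the first
#' `window - 1` positions average over the samples available so far.
#'
#' @param y numeric vector, or matrix smoothed row-wise.
#' @param window window length in timesteps.
#' @return smoothed object of the same shape.
#' @export
moving_average <- function(y, window = 300L) {
  stopifnot(window >= 1)
  window <- as.integer(window)
  if (is.matrix(y)) {
    return(t(apply(y, 1, moving_average, window = window)))
  }
  n <- length(y)
  cs <- cumsum(y)
  full <- seq_len(n) >= window
  out <- numeric(n)
  out[!full] <- cs[!full] / seq_len(sum(!full))
  idx <- which(full)
  out[idx] <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
  out
}

#' Operating-threshold selection by TPR/TNR balance
#'
#' Scans all candidate thresholds (midpoints between consecutive distinct
#' sorted scores) and returns the one minimizing |TPR - TNR|, where a
#' sample is called positive when its score exceeds the threshold. Ties
#' are broken toward the larger threshold.
#'
#' @param scores numeric detection scores.
#' @param labels binary labels (1/TRUE = positive class).
#' @return the selected threshold.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to select a threshold")
  }
  u <- sort(unique(scores))
  if (length(u) == 1L) return(u)
  cand <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(labels)
  nneg <- sum(!labels)
  g <- match(scores, u)
  cum_pos <- cumsum(tabulate(g[labels], nbins = length(u)))
  cum_neg <- cumsum(tabulate(g[!labels], nbins = length(u)))
  i <- seq_len(length(u) - 1L)       # candidate i lies in (u[i], u[i+1])
  tpr <- (npos - cum_pos[i]) / npos  # positives with score > cand[i]
  tnr <- cum_neg[i] / nneg           # negatives with score <= cand[i]
  crit <- abs(tpr - tnr)
  best <- which(crit <= min(crit) + 1e-12)
  cand[max(best)]
}

#' Decode two-channel scores into gait patterns
#'
#' Thresholds the smoothed TO and TL channels and maps the resulting bit
#' pair to one of the four gait classes.
#'
#' @param y 2 x M matrix of (smoothed) channel outputs (rows TO, TL).
#' @param thresholds numeric of length 2: the TO and TL thresholds.
#' @return character vector of pattern codes, length M.
#' @export
decode_patterns <- function(y, thresholds) {
  stopifnot(is.matrix(y), nrow(y) == 2L, length(thresholds) == 2L)
  onehot_to_pattern(y[1, ] > thresholds[1], y[2, ] > thresholds[2])
}

#' Readout hyperparameter grid search
#'
#' Small helper evaluating mean cross-validated AUC over a grid of leak
#' and ridge values for a set of recordings (activation matrices with
#' label streams), using the same contiguous k-fold protocol as
#' [evaluate_readout()].
#'
#' @param activations list of raw N x M activation matrices (one per
#'   recording).
#' @param labels list of per-recording pattern codes (constant labels may
#'   be given as a single code).
#' @param alphas,betas grids of leaking rates and ridge parameters.
#' @param k number of folds.
#' @param avg_window moving-average window.
#' @param transient initial timesteps to discard.
#' @return data.frame of (alpha, beta, auc_to, auc_tl, auc_mean).
#' @export
readout_grid_search <- function(activations, labels,
                                alphas = c(0.05, 0.2, 0.5, 1),
                                betas = c(1e-6, 1e-3, 1, 1e3),
                                k = 4, avg_window = 300L,
                                transient = 1000L) {
  grid <- expand.grid(alpha = alphas, beta = betas)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- evaluate_readout(activations, labels, alpha = grid$alpha[i],
                            beta = grid$beta[i], k = k,
                            avg_window = avg_window, transient = transient)
    data.frame(alpha = grid$alpha[i], beta = grid$beta[i],
               auc_to = rep$mean_auc[["TO"]], auc_tl = rep$mean_auc[["TL"]],
               auc_mean = mean(rep$mean_auc))
  })
  do.call(rbind, res)
}
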