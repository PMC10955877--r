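#' Contiguous k-fold splits of a recording
#'
#' Splits the M timesteps of a recording into k contiguous, (nearly)
#' equal-length segments; remainder samples go to the last fold. Split s
#' uses fold s for testing and the others for training, so every sample
#' is tested exactly once across the k splits. Contiguous (time-block)
#' folds avoid leakage through the moving-average smoother.
#'
#' @param M number of timesteps.
#' @param k number of folds.
#' @return list with `fold` (length-M fold assignment), `sizes`, and `k`.
#' @export
kfold_splits <- function(M, k = 4L) {
  if (M < k) stop("recording too short: M = ", M, " < k = ", k)
  base <- floor(M / k)
  sizes <- rep(base, k)
  sizes[k] <- M - base * (k - 1)
  list(fold = rep(seq_len(k), sizes), sizes = sizes, k = as.integer(k))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique score values (samples
#' with tied scores enter the curve simultaneously) and integrates the
#' resulting ROC by the trapezoid rule, which equals the Mann-Whitney
#' pair-counting statistic with ties counted 1/2.
#'
#' @param scores numeric detection scores (larger = more positive).
#' @param labels binary labels (1/TRUE = positive).
#' @return list with `fpr`, `tpr` (curve vertices, from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("ROC undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)       # last index of each tied group
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  tpr <- c(0, tp / sum(l))
  fpr <- c(0, fp / sum(!l))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Row-normalized confusion matrix
#'
#' @param predicted,prescribed equal-length vectors of gait pattern codes;
#'   rows of the result are the prescribed (true) patterns, columns the
#'   predictions.
#' @return 4 x 4 matrix of percentages; each row with any samples sums
#'   to 100.
#' @export
confusion_matrix <- function(predicted, prescribed) {
  if (length(predicted) != length(prescribed)) {
    stop("predicted and prescribed lengths differ")
  }
  lv <- gait_patterns()
  tab <- table(factor(prescribed, levels = lv),
               factor(predicted, levels = lv))
  rs <- rowSums(tab)
  pct <- sweep(tab, 1, pmax(rs, 1), "/") * 100
  m <- matrix(as.numeric(pct), 4, 4, dimnames = list(lv, lv))
  m
}

#' Box-plot style summary of AUC values
#'
#' Median, first/third quartiles (linear-interpolation quantiles),
#' whiskers at the most extreme values within 1.5 interquartile ranges of
#' the box, and the outliers beyond them.
#'
#' @param values numeric vector (e.g. per-condition AUCs).
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
auc_summary <- function(values) {
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = values[!inside], n = length(values))
}

# ---- Cross-validated evaluation engine -------------------------------------

# Trim / expand a label stream to M timesteps.
align_labels <- function(labels, M) {
  labels <- match_pattern(labels)
  if (length(labels) == 1L) return(rep(labels, M))
  if (length(labels) < M) stop("label stream shorter than feature stream")
  labels[(length(labels) - M + 1L):length(labels)]
}

#' Cross-validated two-channel evaluation
#'
#' The shared evaluation protocol for all three classifiers. Each
#' recording's feature stream is split into `k` contiguous folds; for
#' every split, a model is fitted on the training folds pooled across
#' recordings, raw channel outputs are smoothed by a causal moving
#' average (restarted at every fold boundary), detection thresholds are
#' selected on the training folds by the |TPR - TNR| rule, and ROC/AUC is
#' computed on the pooled test folds. Reported AUCs are the means over
#' the k splits; the confusion matrix pools the decoded test timesteps of
#' all splits.
#'
#' @param features list with one element per recording: either a feature
#'   matrix (columns are timesteps, transient already removed) or a lazy
#'   builder `list(n = <timesteps>, build = function())` that materializes
#'   it on demand (used where holding every recording's features at once
#'   would be wasteful).
#' @param labels list of per-recording pattern codes (a single code per
#'   recording, or one per timestep).
#' @param fit function(X, Y) returning a fitted model, where Y is the
#'   2 x M one-hot target matrix.
#' @param predict function(model, X) returning 2 x m channel scores.
#' @param k number of folds.
#' @param avg_window moving-average window (timesteps).
#' @param fit_stride subsampling stride for the pooled training columns
#'   (1 = use every training timestep). Scoring, smoothing, thresholds
#'   and the test metrics always use every timestep.
#' @return object of class `gait_eval`: per-split AUCs and ROC curves,
#'   mean AUC per channel, per-split thresholds, pooled 4 x 4 confusion
#'   matrix (%), and timestep counts.
#' @export
cv_evaluate <- function(features, labels, fit, predict, k = 4L,
                        avg_window = 300L, fit_stride = 1L) {
  stopifnot(length(features) == length(labels))
  R <- length(features)
  # a feature element is either a p x M matrix or a lazy builder
  # list(n = M, build = function() matrix); lazy builders keep the peak
  # memory footprint at roughly one split's training matrix
  feat_n <- function(f) if (is.matrix(f)) ncol(f) else f$n
  feat_get <- function(f) if (is.matrix(f)) f else f$build()
  lab <- vector("list", R)
  folds <- vector("list", R)
  for (r in seq_len(R)) {
    M <- feat_n(features[[r]])
    lab[[r]] <- align_labels(labels[[r]], M)
    folds[[r]] <- kfold_splits(M, k)
  }
  channels <- c("TO", "TL")
  auc <- matrix(NA_real_, k, 2, dimnames = list(NULL, channels))
  thr <- matrix(NA_real_, k, 2, dimnames = list(NULL, channels))
  roc <- vector("list", k)
  pred_all <- character(0)
  true_all <- character(0)

  for (s in seq_len(k)) {
    # pass 1: assemble the pooled training matrix (preallocated)
    tr_idx <- lapply(folds, function(fl) {
      w <- which(fl$fold != s)
      w[seq(1L, length(w), by = fit_stride)]
    })
    tr_cols <- lengths(tr_idx)
    tr_lab_all <- character(sum(tr_cols))
    Xtr <- NULL
    at <- 0L
    for (r in seq_len(R)) {
      Fr <- feat_get(features[[r]])
      if (is.null(Xtr)) Xtr <- matrix(0, nrow(Fr), sum(tr_cols))
      idx <- at + seq_len(tr_cols[r])
      Xtr[, idx] <- Fr[, tr_idx[[r]], drop = FALSE]
      tr_lab_all[idx] <- lab[[r]][tr_idx[[r]]]
      at <- at + tr_cols[r]
    }
    model <- fit(Xtr, pattern_to_onehot(tr_lab_all))
    rm(Xtr)

    # pass 2: smoothed scores per contiguous fold segment
    tr_sc <- NULL; tr_lab <- character(0)
    te_sc <- NULL; te_lab <- character(0)
    for (r in seq_len(R)) {
      Fr <- feat_get(features[[r]])
      for (f in seq_len(k)) {
        idx <- which(folds[[r]]$fold == f)
        y <- predict(model, Fr[, idx, drop = FALSE])
        y <- moving_average(y, avg_window)
        if (f == s) {
          te_sc <- cbind(te_sc, y); te_lab <- c(te_lab, lab[[r]][idx])
        } else {
          tr_sc <- cbind(tr_sc, y); tr_lab <- c(tr_lab, lab[[r]][idx])
        }
      }
    }

    oh_tr <- pattern_to_onehot(tr_lab)
    oh_te <- pattern_to_onehot(te_lab)
    roc[[s]] <- list()
    for (ch in 1:2) {
      if (length(unique(oh_tr[ch, ])) < 2L || length(unique(oh_te[ch, ])) < 2L) {
        # channel degenerate in this condition (e.g. a two-pattern cohort)
        thr[s, ch] <- if (all(oh_tr[ch, ] == 0)) Inf else -Inf
        next
      }
      thr[s, ch] <- select_threshold(tr_sc[ch, ], oh_tr[ch, ])
      rc <- roc_auc(te_sc[ch, ], oh_te[ch, ])
      auc[s, ch] <- rc$auc
      roc[[s]][[channels[ch]]] <- rc[c("fpr", "tpr")]
    }
    pred_all <- c(pred_all, decode_patterns(te_sc, thr[s, ]))
    true_all <- c(true_all, te_lab)
  }

  structure(list(
    per_split_auc = auc,
    mean_auc = colMeans(auc),
    thresholds = thr,
    roc = roc,
    confusion = confusion_matrix(pred_all, true_all),
    n_test = length(true_all),
    k = k, avg_window = as.integer(avg_window)
  ), class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  cat(sprintf("<gait_eval> %d-fold CV, %d test timesteps\n", x$k, x$n_test))
  cat(sprintf("  mean AUC: TO = %.3f, TL = %.3f\n",
              x$mean_auc[["TO"]], x$mean_auc[["TL"]]))
  cat("  confusion (% by prescribed row):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Evaluate a ridge readout on reservoir activations
#'
#' @param activations list of raw N x M activation matrices (or
#'   `reservoir_trace` objects), one per recording.
#' @param labels list of per-recording pattern codes.
#' @param alpha leaking rate of the readout integrator.
#' @param beta ridge regularization.
#' @param k folds; `avg_window` moving-average window; `transient`
#'   initial timesteps discarded per recording.
#' @param avg_window moving-average window (timesteps).
#' @param transient initial timesteps to discard.
#' @return a `gait_eval` (see [cv_evaluate()]).
#' @export
evaluate_readout <- function(activations, labels, alpha = 0.02, beta = 1e-2,
                             k = 4L, avg_window = 300L, transient = 1000L) {
  feats <- lapply(activations, activation_matrix, alpha = alpha,
                  transient = transient)
  cv_evaluate(feats, labels,
              fit = function(X, Y) ridge_train(X, Y, beta),
              predict = function(W, X) W %*% X,
              k = k, avg_window = avg_window)
}

#' Evaluate the ESN baseline
#'
#' @param inputs list of acceleration sequences (g) at the timestep rate.
#' @param labels list of per-recording pattern codes.
#' @param params an [esn_params()].
#' @param beta ridge regularization of the readout.
#' @inheritParams evaluate_readout
#' @return a `gait_eval`.
#' @export
evaluate_esn <- function(inputs, labels, params = esn_params(),
                         beta = 1e-2, k = 4L, avg_window = 300L,
                         transient = 1000L) {
  w <- esn_init_weights(params)
  feats <- lapply(inputs, esn_features, params = params, w = w,
                  transient = transient)
  cv_evaluate(feats, labels,
              fit = function(X, Y) ridge_train(X, Y, beta),
              predict = function(W, X) W %*% X,
              k = k, avg_window = avg_window)
}

#' Evaluate the logistic-regression baseline
#'
#' Feature standardization statistics and the logistic fits are computed
#' on the training folds of each split only. Because adjacent window
#' features overlap by all but one sample, the logistic fit uses every
#' `fit_stride`-th training timestep (scoring and evaluation remain
#' per-timestep); the default stride of 3 leaves the optimum essentially
#' unchanged at a third of the cost.
#'
#' @param inputs list of acceleration sequences (g) at the timestep rate.
#' @param labels list of per-recording pattern codes.
#' @param params an [lr_params()].
#' @param sample_rate timestep rate (Hz).
#' @param fit_stride training-timestep stride for the logistic fits.
#' @inheritParams evaluate_readout
#' @return a `gait_eval`.
#' @export
evaluate_lr <- function(inputs, labels, params = lr_params(),
                        sample_rate = 142.85, k = 4L, avg_window = 300L,
                        transient = 1000L, fit_stride = 3L) {
  # keep only the filtered signals; window matrices are materialized per
  # recording on demand (they are indexed views of the filtered signal)
  feats <- lapply(inputs, function(u) {
    uf <- lr_filter(u, sample_rate, params)
    if (length(uf) < transient + 1L) {
      stop("input too short: need more than ", transient, " samples")
    }
    list(n = length(uf) - transient,
         build = function() lr_window_matrix(uf, params, transient))
  })
  cv_evaluate(feats, labels,
              fit = function(X, Y) lr_fit(X, Y, params),
              predict = function(m, X) lr_predict(m, X),
              k = k, avg_window = avg_window, fit_stride = fit_stride)
}
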