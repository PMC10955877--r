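# Deliberate-leak variant of the logistic pipeline for isolation tests:
# features are standardized GLOBALLY (train + test) before entering the
# CV engine, and the fit does not re-standardize. Comparing against the
# clean evaluate_lr() path shows the training-fold-only statistics are
# load-bearing.
lr_leak_fit_predict <- function(p) {
  fit <- function(X, Y) {
    Xs <- t(X); n <- nrow(Xs); lam <- 1 / (n * p$C)
    fits <- lapply(1:2, function(ch) {
      y <- Y[ch, ]
      if (length(unique(y)) == 1L) {
        return(structure(list(p = mean(y)), class = "lr_const"))
      }
      glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                     lambda = lam * 10^seq(3, 0, -1),
                     standardize = FALSE, thresh = 1e-8)
    })
    list(fits = fits, lambda = lam)
  }
  predict <- function(m, X) {
    Xs <- t(X)
    t(vapply(1:2, function(ch) {
      f <- m$fits[[ch]]
      if (inherits(f, "lr_const")) return(rep(f$p, nrow(Xs)))
      as.numeric(stats::predict(f, newx = Xs, s = m$lambda,
                                type = "response"))
    }, numeric(nrow(Xs))))
  }
  list(fit = fit, predict = predict)
}

# standardize a list of feature matrices with pooled (leaky) statistics
standardize_globally <- function(feats) {
  allF <- do.call(cbind, feats)
  ctr <- rowMeans(allF)
  scl <- apply(allF, 1, sd)
  scl[scl == 0] <- 1
  lapply(feats, function(f) (f - ctr) / scl)
}
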