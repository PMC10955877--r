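# Independent oracles used to freeze expected values.

# AUC by exhaustive pair counting (Mann-Whitney; ties count 1/2).
auc_pairs <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Ridge solution by direct numerical minimization of
# ||Y - W X||_F^2 + beta ||W||_F^2 (generic convex solver).
ridge_optim <- function(X, Y, beta) {
  obj <- function(w) {
    W <- matrix(w, nrow(Y), nrow(X))
    sum((Y - W %*% X)^2) + beta * sum(W^2)
  }
  gr <- function(w) {
    W <- matrix(w, nrow(Y), nrow(X))
    as.numeric(2 * (W %*% X - Y) %*% t(X) + 2 * beta * W)
  }
  fit <- stats::optim(numeric(nrow(Y) * nrow(X)), obj, gr,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  matrix(fit$par, nrow(Y), nrow(X))
}

# L2-penalized logistic regression by damped Newton iteration on the
# objective sum(log(1 + exp(-z))) ... written as C * logloss + 0.5||w||^2
# scaled to glmnet's (1/n) loss + (lambda/2)||w||^2 parametrisation.
logistic_newton <- function(X, y, lambda, maxit = 100) {
  # X: n x p (no intercept column); intercept unpenalized
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(1, X)
  pen <- c(0, rep(lambda * n, p))     # objective: sum loss + (n*lambda/2)||w||^2
  w <- numeric(p + 1)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(Xa %*% w)
    mu <- 1 / (1 + exp(-eta))
    g <- as.numeric(t(Xa) %*% (mu - y)) + pen * w
    W <- mu * (1 - mu)
    H <- t(Xa * W) %*% Xa + diag(pen, p + 1)
    step <- solve(H, g)
    w <- w - step
    if (max(abs(g)) < 1e-12) break
  }
  w
}

logistic_objective <- function(X, y, w, lambda) {
  eta <- as.numeric(cbind(1, X) %*% w)
  # numerically stable log(1 + exp(-(2y-1)*eta))
  z <- -(2 * y - 1) * eta
  loss <- sum(ifelse(z > 30, z, log1p(exp(z))))
  loss / nrow(X) + lambda / 2 * sum(w[-1]^2)
}

# third central moment (skewness numerator), used as the phase-coupling
# observable of the gait waveforms
third_moment <- function(x) mean((x - mean(x))^3)
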