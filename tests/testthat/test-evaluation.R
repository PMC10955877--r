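test_that("contiguous folds partition the recording with remainder rule", {
  f <- kfold_splits(8, 4)
  expect_equal(f$sizes, c(2, 2, 2, 2))
  expect_equal(f$fold[1:2], c(1, 1))

  f10 <- kfold_splits(10, 4)
  expect_equal(f10$sizes, c(2, 2, 2, 4))
  # every sample in exactly one fold; folds are contiguous blocks
  expect_equal(sort(unique(f10$fold)), 1:4)
  expect_true(all(diff(f10$fold) >= 0))
  expect_length(f10$fold, 10)

  expect_error(kfold_splits(3, 4), "too short")
})

test_that("trapezoidal AUC equals the pair-counting oracle", {
  # perfect and random limits
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  set.seed(3)
  sc <- rnorm(4000)
  lb <- rbinom(4000, 1, 0.5)
  expect_equal(roc_auc(sc, lb)$auc, 0.5, tolerance = 0.03)

  # exhaustive pair counting on many small instances, with ties
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    sc <- round(rnorm(n), sample(0:1, 1))   # coarse rounding forces ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, auc_pairs(sc, lb), tolerance = 1e-12)
  }

  # single swap example checked against the pair count
  sc <- c(1, 2, 3, 4, 5, 6)
  lb <- c(0, 0, 1, 0, 1, 1)
  expect_equal(roc_auc(sc, lb)$auc, auc_pairs(sc, lb))
  expect_equal(roc_auc(sc, lb)$auc, 8 / 9)

  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC curve agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- round(rnorm(200), 1)
  lb <- rbinom(200, 1, 0.4)
  ours <- roc_auc(sc, lb)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    lb, sc, levels = c(0, 1), direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("confusion matrix is row-normalized percent by prescribed class", {
  pred <- c("N", "N", "TO", "TL", "TL", "TL", "TOTL")
  true <- c("N", "N", "TO", "TL", "TL", "TL", "TL")
  cm <- confusion_matrix(pred, true)
  expect_equal(cm["N", "N"], 100)
  expect_equal(cm["TL", ], c(N = 0, TO = 0, TL = 75, TOTL = 25))
  expect_true(all(abs(rowSums(cm)[rowSums(cm) > 0] - 100) < 0.01))

  # all predicted N -> first column is 100 in occupied rows
  cm2 <- confusion_matrix(rep("N", 4), gait_patterns())
  expect_equal(unname(cm2[, "N"]), rep(100, 4))

  expect_error(confusion_matrix("N", c("N", "TO")), "lengths differ")
})

test_that("box summary uses interpolation quantiles and 1.5 IQR whiskers", {
  s <- auc_summary(1:8)
  expect_equal(s$median, 4.5)
  expect_equal(s$q1, 2.75)
  expect_equal(s$q3, 6.25)
  expect_equal(s$whisker_low, 1)      # all points inside the fences
  expect_equal(s$whisker_high, 8)
  expect_length(s$outliers, 0)

  s1 <- auc_summary(5)
  expect_equal(s1$median, 5)
  expect_equal(s1$q3 - s1$q1, 0)

  so <- auc_summary(c(1:8, 100))
  expect_equal(so$outliers, 100)
  expect_equal(so$whisker_high, 8)
})

test_that("cross-validated readout evaluation separates a designed cohort", {
  # small synthetic activation streams whose class information is a mean
  # shift: the engine should recover it essentially perfectly
  set.seed(21)
  mk <- function(pat) {
    oh <- pattern_to_onehot(pat)
    base <- matrix(rnorm(6 * 1400, sd = 0.3), 6, 1400)
    base[1:3, ] <- base[1:3, ] + oh[1]
    base[4:6, ] <- base[4:6, ] + oh[2]
    base
  }
  pats <- rep(gait_patterns(), 2)
  acts <- lapply(pats, mk)
  ev <- evaluate_readout(acts, as.list(pats), alpha = 0.5, beta = 1e-3,
                         transient = 100, avg_window = 50)
  expect_s3_class(ev, "gait_eval")
  expect_equal(dim(ev$per_split_auc), c(4, 2))
  expect_gt(ev$mean_auc[["TO"]], 0.99)
  expect_gt(ev$mean_auc[["TL"]], 0.99)
  expect_true(all(abs(rowSums(ev$confusion) - 100) < 0.01))
  expect_gt(mean(diag(ev$confusion)), 90)
})

test_that("reported metric is the mean over the four splits", {
  set.seed(4)
  acts <- lapply(rep(gait_patterns(), 2), function(pat) {
    oh <- pattern_to_onehot(pat)
    m <- matrix(rnorm(4 * 1200, sd = 1), 4, 1200)
    m[1:2, ] <- m[1:2, ] + 0.8 * oh[1]
    m[3:4, ] <- m[3:4, ] + 0.8 * oh[2]
    m
  })
  ev <- evaluate_readout(acts, as.list(rep(gait_patterns(), 2)),
                         alpha = 1, beta = 1e-3, transient = 100,
                         avg_window = 20)
  expect_equal(unname(ev$mean_auc), unname(colMeans(ev$per_split_auc)))
})

test_that("training-fold standardization leak changes the LR result", {
  # deliberately leaking test-fold statistics into the feature
  # standardization must change the outcome relative to the clean path
  cohort <- generate_cohort(2, speeds = 0.54, patterns = c("N", "TO"),
                            master_seed = 31, duration = 25)
  inputs <- lapply(cohort$trials, `[[`, "samples")
  labels <- as.list(cohort$manifest$pattern)
  p <- lr_params(C = 1e-3)    # strong penalty: scaling matters
  clean <- evaluate_lr(inputs, labels, params = p, transient = 800,
                       avg_window = 50)

  # mutated pipeline: pooled (train + test) standardization statistics
  feats <- lapply(inputs, lr_feature_matrix, p = p, transient = 800)
  leaked <- standardize_globally(feats)
  fp <- lr_leak_fit_predict(p)
  mut <- cv_evaluate(leaked, labels, fit = fp$fit, predict = fp$predict,
                     avg_window = 50, fit_stride = 3L)
  expect_false(isTRUE(all.equal(clean$thresholds, mut$thresholds)))
})
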