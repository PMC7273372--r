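test_that("confusion matrix counts the four-way cross-classification", {
  truth <- rep(c("positive", "negative"), c(4, 6))
  cm <- confusion_matrix(truth, truth)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(4L, 6L, 0L, 0L))

  flipped <- ifelse(truth == "positive", "negative", "positive")
  cmf <- confusion_matrix(truth, flipped)
  expect_equal(c(cmf$tp, cmf$tn, cmf$fp, cmf$fn), c(0L, 0L, 6L, 4L))

  set.seed(61)
  t2 <- sample(c("positive", "negative"), 200, replace = TRUE)
  p2 <- sample(c("positive", "negative"), 200, replace = TRUE)
  cm2 <- confusion_matrix(t2, p2)
  # four-counter brute-force tally
  tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in 1:200) {
    key <- if (t2[i] == "positive" && p2[i] == "positive") "tp"
      else if (t2[i] == "negative" && p2[i] == "negative") "tn"
      else if (t2[i] == "negative") "fp" else "fn"
    tally[key] <- tally[key] + 1
  }
  expect_equal(c(cm2$tp, cm2$tn, cm2$fp, cm2$fn), unname(tally))
  expect_equal(cm2$tp + cm2$tn + cm2$fp + cm2$fn, 200L)

  expect_error(confusion_matrix(t2, p2[-1]), "different lengths")
  expect_error(confusion_matrix("enzyme", "positive"), "labels")
})

test_that("ACC/SP/SE follow the package's stated (reversed) convention", {
  cm <- structure(list(tp = 3L, fn = 1L, tn = 4L, fp = 2L),
                  class = "enzid_confusion")
  m <- metrics(cm)
  expect_equal(m$acc, 70)
  expect_equal(m$sp_paper, 0.75)        # TP/(TP+FN): rate on positives
  expect_equal(m$se_paper, 2 / 3)       # TN/(TN+FP): rate on negatives
  # alias contract: standard names map onto the same quantities
  expect_equal(m$sensitivity, m$sp_paper)
  expect_equal(m$specificity, m$se_paper)

  sym <- structure(list(tp = 25L, tn = 25L, fp = 25L, fn = 25L),
                   class = "enzid_confusion")
  ms <- metrics(sym)
  expect_equal(ms$acc, 50)
  expect_equal(ms$sp_paper, 0.5)
  expect_equal(ms$se_paper, 0.5)

  perfect <- confusion_matrix(rep(c("positive", "negative"), 5),
                              rep(c("positive", "negative"), 5))
  mp <- metrics(perfect)
  expect_equal(mp$acc, 100)
  expect_equal(mp$sp_paper, 1)
  expect_equal(mp$se_paper, 1)
})

test_that("zero-denominator ratios are NA with a warning, never 0 or 1", {
  cm <- structure(list(tp = 0L, fn = 0L, tn = 5L, fp = 3L),
                  class = "enzid_confusion")
  expect_warning(m <- metrics(cm), "undefined")
  expect_true(is.na(m$sp_paper))
  expect_false(is.na(m$se_paper))
  empty <- structure(list(tp = 0L, fn = 0L, tn = 0L, fp = 0L),
                     class = "enzid_confusion")
  expect_error(metrics(empty), "empty")
})

test_that("pooled CV accuracy equals the sample-weighted mean of fold accuracies", {
  f <- separable_features(12, gap = 2, seed = 31)
  cv <- cross_validate(f, svm_config(cost = 1, gamma = 0.5), n_folds = 4,
                       seed = 3)
  per <- tidy(cv)
  n_fold <- per$tp + per$tn + per$fp + per$fn
  expect_equal(glance(cv)$acc, sum(per$acc * n_fold) / sum(n_fold))
})

test_that("ROC endpoints, monotonicity and degenerate cases are correct", {
  r <- roc_curve(c("positive", "positive", "negative", "negative"),
                 c(4, 3, 2, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)

  # all-tied scores collapse to the chance diagonal
  tied <- roc_curve(rep(c("positive", "negative"), 5), rep(0.3, 10))
  expect_equal(tied$auc, 0.5)
  expect_equal(nrow(tied$points), 2L)
  expect_equal(tied$points$fpr, c(0, 1))
  expect_equal(tied$points$tpr, c(0, 1))

  expect_error(roc_curve(rep("positive", 3), 1:3), "both classes")
  # coordinates never decrease along the sweep
  set.seed(71)
  rr <- roc_curve(sample(c("positive", "negative"), 60, replace = TRUE,
                         prob = c(.4, .6)),
                  round(rnorm(60), 1))
  expect_true(all(diff(rr$points$fpr) >= 0))
  expect_true(all(diff(rr$points$tpr) >= 0))
})

test_that("trapezoidal AUC equals the rank-pair oracle and pROC", {
  set.seed(83)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("positive", "negative")
    score <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    r <- roc_curve(truth, score)
    expect_equal(r$auc, oracle_auc(truth, score))
  }
  # independent library cross-check on one tie-rich case
  truth <- sample(c("positive", "negative"), 80, replace = TRUE)
  score <- round(rnorm(80), 1)
  r <- roc_curve(truth, score)
  p <- pROC::roc(response = truth, predictor = score,
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(p)))
})

test_that("AUC is antisymmetric under score negation when tie-free", {
  set.seed(89)
  truth <- sample(c("positive", "negative"), 50, replace = TRUE)
  truth[1:2] <- c("positive", "negative")
  score <- rnorm(50)
  expect_equal(roc_curve(truth, score)$auc + roc_curve(truth, -score)$auc, 1)
})

test_that("metric and ROC writers emit the documented plain-text formats", {
  m <- metrics(confusion_matrix(rep(c("positive", "negative"), 5),
                                rep(c("positive", "negative"), 5)))
  jf <- tempfile(fileext = ".json")
  write_metrics(m, jf)
  got <- jsonlite::read_json(jf)
  expect_equal(got$acc, 100)
  r <- roc_curve(rep(c("positive", "negative"), 5), 10:1)
  tf <- tempfile(fileext = ".tsv")
  write_roc(r, tf)
  pts <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(names(pts), c("fpr", "tpr"))
})
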