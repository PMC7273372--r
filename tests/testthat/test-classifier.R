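test_that("svm_config validates and the log2 grids are as documented", {
  expect_error(svm_config(cost = -1))
  expect_error(svm_config(gamma = 0))
  g <- log2_grid("fine")
  expect_equal(range(g$log2c), c(-5, 15))
  expect_equal(range(g$log2gamma), c(-15, 8))
  expect_equal(diff(g$log2c)[1], 0.2)
  expect_true(any(abs(g$log2gamma - 7.2) < 1e-9))  # 2^7.2 is interior
})

test_that("a separable problem is fit perfectly and deterministically", {
  f <- separable_features(20)
  fit <- svm_train(f, svm_config(cost = 1, gamma = 0.5))
  pr <- predict(fit, f)
  expect_equal(as.character(pr$label), as.character(f$label))
  # positive decision scores go with the positive class
  expect_true(all(pr$score[f$label == "positive"] > 0))
  expect_true(all(pr$score[f$label == "negative"] < 0))
  # refitting and re-predicting reproduces the scores exactly
  pr2 <- predict(svm_train(f, svm_config(cost = 1, gamma = 0.5)), f)
  expect_identical(pr$score, pr2$score)

  single <- f[f$label == "positive", ]
  expect_error(svm_train(single, svm_config()), "single class")
})

test_that("fold assignment is a stratified partition for every seed", {
  labs <- factor(rep(c("positive", "negative"), c(30, 45)),
                 levels = c("positive", "negative"))
  for (seed in 1:10) {
    folds <- make_folds(labs, n_folds = 5, seed = seed)
    expect_equal(sort(unique(folds)), 1:5)
    expect_equal(length(folds), 75L)          # every sample in exactly one fold
    expect_true(all(table(folds) == 15))
    # stratification: each fold holds 6 positives and 9 negatives
    expect_true(all(table(folds[labs == "positive"]) == 6))
  }
  expect_identical(make_folds(labs, 5, seed = 3), make_folds(labs, 5, seed = 3))
  expect_error(make_folds(labs, 1, 1), "between 2")
  expect_error(make_folds(labs, 76, 1), "between 2")
  expect_error(make_folds(labs, 40, 1), "smaller class")
  # unstratified folds allowed beyond the smaller class size
  expect_equal(sort(unique(make_folds(labs, 40, 1, stratified = FALSE))), 1:40)
})

test_that("cross-validation pools fold confusions and is seed-reproducible", {
  f <- separable_features(15)
  cv <- cross_validate(f, svm_config(cost = 2, gamma = 0.5), n_folds = 5,
                       seed = 11)
  expect_s3_class(cv, "enzid_cv")
  pooled <- cv$pooled
  sums <- colSums(cv$folds[, c("tp", "tn", "fp", "fn")])
  expect_equal(unname(sums),
               c(pooled$tp, pooled$tn, pooled$fp, pooled$fn))
  expect_equal(sum(sums), nrow(f))
  expect_equal(nrow(cv$predictions), nrow(f))
  expect_setequal(cv$predictions$id, f$id)

  cv2 <- cross_validate(f, svm_config(cost = 2, gamma = 0.5), n_folds = 5,
                        seed = 11)
  expect_equal(cv$predictions, cv2$predictions)
  expect_equal(glance(cv), glance(cv2))
  expect_equal(nrow(tidy(cv)), 5L)
})

test_that("leave-one-out is the n_folds = n limiting case", {
  f <- separable_features(5)  # 10 samples
  cv <- cross_validate(f, svm_config(cost = 2, gamma = 0.5), n_folds = 10,
                       seed = 1, stratified = FALSE)
  expect_equal(nrow(cv$folds), 10L)
  expect_true(all(cv$folds$tp + cv$folds$tn + cv$folds$fp + cv$folds$fn == 1))
})

test_that("pure-noise features score near the majority rate", {
  set.seed(55)
  x <- matrix(runif(100 * 10), ncol = 10)
  f <- as_feature_tbl(x, rep(c("positive", "negative"), each = 50))
  cv <- cross_validate(f, svm_config(cost = 1, gamma = 1), n_folds = 6,
                       seed = 2)
  # binomial sampling at n = 100, p = 0.5: 4 sd = 20 percentage points
  expect_lt(abs(glance(cv)$acc - 50), 20)
})

test_that("grid search parameterizes points as c = 2^a, gamma = 2^b", {
  f <- separable_features(10)
  gs <- grid_search(f, log2c = 0.2, log2gamma = 7.2, n_folds = 4, seed = 1)
  expect_equal(round(gs$best_config$cost, 4), 1.1487)
  expect_equal(round(gs$best_config$gamma, 4), 147.0334)
  expect_equal(nrow(gs$grid), 1L)
})

test_that("grid search reproduces pointwise CV and picks the tie-break argmax", {
  f <- separable_features(12, gap = 4, seed = 77)
  gs <- grid_search(f, log2c = c(-2, 0, 2), log2gamma = c(-3, 0),
                    n_folds = 4, seed = 9)
  expect_equal(nrow(gs$grid), 6L)
  # every grid row equals an independent re-run with the same seed
  for (i in seq_len(nrow(gs$grid))) {
    cv <- cross_validate(f, svm_config(cost = gs$grid$cost[i],
                                       gamma = gs$grid$gamma[i]),
                         n_folds = 4, seed = 9)
    expect_equal(gs$grid$acc[i], glance(cv)$acc)
  }
  # argmax with ties resolved toward smaller log2c, then smaller log2gamma
  top <- gs$grid[gs$grid$acc == max(gs$grid$acc), ]
  top <- top[order(top$log2c, top$log2gamma), ]
  expect_equal(gs$best[, c("log2c", "log2gamma")],
               top[1, c("log2c", "log2gamma")])
  # separable data: some point reaches pooled CV accuracy 100%
  expect_equal(max(gs$grid$acc), 100)
  # bit-reproducible argmax
  gs2 <- grid_search(f, log2c = c(-2, 0, 2), log2gamma = c(-3, 0),
                     n_folds = 4, seed = 9)
  expect_equal(gs$best, gs2$best)
})
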