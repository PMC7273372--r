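test_that("two-group F statistic matches hand arithmetic and its MSB/MSW parts", {
  x <- as_feature_tbl(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1),
                      rep(c("positive", "negative"), each = 3))
  out <- anova_f(x)
  expect_equal(out$msb, 13.5)
  expect_equal(out$msw, 1)
  expect_equal(out$F, 13.5)
  # and the pooled-variance t oracle agrees (t = 3.674, t^2 = 13.5)
  expect_equal(oracle_f_from_t(c(1, 2, 3), c(4, 5, 6)), 13.5)
})

test_that("F equals squared pooled-variance t on many random columns", {
  set.seed(17)
  n1 <- 9; n2 <- 14
  x <- matrix(rnorm(200 * (n1 + n2)), ncol = 200)
  labs <- rep(c("positive", "negative"), c(n1, n2))
  got <- anova_f(as_feature_tbl(x, labs))
  expected <- apply(x, 2, function(col) {
    oracle_f_from_t(col[seq_len(n1)], col[n1 + seq_len(n2)])
  })
  expect_equal(got$F, unname(expected))
})

test_that("degenerate columns get the documented sentinels", {
  x <- as_feature_tbl(
    cbind(const = rep(1, 4), sep = c(0, 0, 1, 1), noise = c(0, 1, 0, 1)),
    rep(c("positive", "negative"), each = 2))
  out <- anova_f(x)
  expect_equal(out$F[out$descriptor == "const"], 0)    # msb = msw = 0
  expect_equal(out$msb[out$descriptor == "const"], 0)
  expect_equal(out$F[out$descriptor == "sep"], Inf)    # msw = 0, msb > 0
  expect_error(anova_f(as_feature_tbl(matrix(1:3, ncol = 1),
                                      c("positive", "negative", "negative"))),
               "at least 2")
})

test_that("F is invariant to shifting and scaling a column", {
  set.seed(23)
  x <- rnorm(20)
  labs <- rep(c("positive", "negative"), each = 10)
  f0 <- anova_f(as_feature_tbl(matrix(x, ncol = 1), labs))$F
  f_shift <- anova_f(as_feature_tbl(matrix(x + 5, ncol = 1), labs))$F
  f_scale <- anova_f(as_feature_tbl(matrix(x * -3.7, ncol = 1), labs))$F
  expect_equal(f_shift, f0)
  expect_equal(f_scale, f0)
})

test_that("ranking is descending, Inf first, ties broken by name", {
  tbl <- tibble::tibble(descriptor = c("AA", "C*C", "D*D"),
                        msb = 1, msw = 1, F = c(5, 10, 1))
  expect_equal(rank_features(tbl)$descriptor, c("C*C", "AA", "D*D"))

  tie <- tibble::tibble(descriptor = c("ZZ", "AA", "MM"),
                        msb = 1, msw = 1, F = c(2, 2, Inf))
  expect_equal(rank_features(tie)$descriptor, c("MM", "AA", "ZZ"))

  set.seed(29)
  big <- tibble::tibble(descriptor = sample(cksaap_descriptors(2), 400),
                        msb = 1, msw = 1, F = round(runif(400), 2))
  got <- rank_features(big)$descriptor
  # independent sort oracle
  oracle <- big$descriptor[order(-big$F, big$descriptor)]
  expect_equal(got, oracle)
  # determinism on repeat
  expect_equal(rank_features(big)$descriptor, got)
})

test_that("planted pairs dominate the ranking at large effect size", {
  hits <- 0L
  for (seed in 1:8) {
    d <- simulate_enzyme_dataset(n_pos = 40, n_neg = 40,
                                 length_range = c(80L, 160L), seed = seed)
    f <- encode_features(d, aac = FALSE, k = 3)
    top <- rank_features(anova_f(f))$descriptor[1:5]
    hits <- hits + all(c("A***A", "L***L") %in% top)
  }
  expect_gte(hits, 8L * 0.95)
})

test_that("incremental selection returns a well-formed curve and best subset", {
  d <- simulate_enzyme_dataset(n_pos = 30, n_neg = 30,
                               length_range = c(60L, 120L), seed = 3)
  sel <- select_incremental(d, k = 3, max_m = 6, n_folds = 3, seed = 5,
                            config = svm_config(cost = 8, gamma = 2))
  expect_s3_class(sel, "enzid_selection")
  expect_equal(sel$curve$m, 1:6)
  expect_equal(sort(sel$ranking$descriptor), sort(cksaap_descriptors(3)))
  expect_equal(sel$best_features[1:20], AA20)
  expect_length(sel$best_features, 20 + sel$best_m)
  # the two planted pairs produce a plateau once both are in
  expect_gte(max(sel$curve$acc), 90)
  # ties go to the smallest m
  expect_equal(sel$best_m, sel$curve$m[which.max(sel$curve$acc)])

  one <- select_incremental(d, k = 3, max_m = 1, n_folds = 3, seed = 5,
                            config = svm_config(cost = 8, gamma = 2))
  expect_equal(nrow(one$curve), 1L)
  expect_equal(one$best_m, 1L)
})

test_that("selection is deterministic and fold-safe mode runs", {
  d <- simulate_enzyme_dataset(n_pos = 20, n_neg = 20,
                               length_range = c(60L, 100L), seed = 9)
  a <- select_incremental(d, k = 3, max_m = 2, n_folds = 4, seed = 7,
                          config = svm_config(cost = 4, gamma = 1))
  b <- select_incremental(d, k = 3, max_m = 2, n_folds = 4, seed = 7,
                          config = svm_config(cost = 4, gamma = 1))
  expect_equal(a$curve, b$curve)
  expect_equal(a$ranking, b$ranking)

  fs <- select_incremental(d, k = 3, max_m = 2, n_folds = 4, seed = 7,
                           config = svm_config(cost = 4, gamma = 1),
                           fold_safe = TRUE)
  expect_equal(fs$curve$m, 1:2)
  expect_true(all(fs$curve$acc >= 0 & fs$curve$acc <= 100))
})

test_that("selection outputs are written as consumable plain text", {
  d <- simulate_enzyme_dataset(n_pos = 15, n_neg = 15,
                               length_range = c(50L, 80L), seed = 13)
  sel <- select_incremental(d, k = 3, max_m = 2, n_folds = 3, seed = 1,
                            config = svm_config(cost = 4, gamma = 1))
  dir <- tempfile()
  paths <- write_selection(sel, dir)
  expect_true(all(file.exists(paths)))
  feats <- readLines(paths["features"])
  # the best-feature list feeds straight back into the encoder
  reenc <- encode_features(d, descriptors = feats)
  expect_equal(feature_names(reenc), feats)
})
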