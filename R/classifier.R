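#' RBF-SVM hyperparameter configuration
#'
#' @param cost Cost (margin/loss trade-off) parameter c > 0.
#' @param gamma RBF kernel width parameter gamma > 0. `NULL` defers to the
#'   libsvm default 1/p at training time (p = number of features).
#' @return A list of class `enzid_svm_config`.
#' @export
#' @examples
#' svm_config(cost = 2^0.2, gamma = 2^7.2)
svm_config <- function(cost = 1, gamma = NULL) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  structure(list(cost = cost, gamma = gamma, kernel = "radial"),
            class = "enzid_svm_config")
}

#' @export
print.enzid_svm_config <- function(x, ...) {
  cat("RBF-SVM config: cost =", format(x$cost),
      " gamma =", if (is.null(x$gamma)) "1/p (default)" else format(x$gamma),
      "\n")
  invisible(x)
}

#' Log2 hyperparameter grids for (c, gamma) search
#'
#' Candidate exponent grids for [grid_search()], which evaluates
#' c = 2^a, gamma = 2^b at every (a, b). The `"fine"` grid steps by 0.2 in
#' both exponents (a in \[-5, 15\], b in \[-15, 8\]); `"coarse"` steps by 2
#' over the same ranges for quick searches, intended to be followed by a
#' fine search around the winner if needed.
#'
#' @param resolution `"coarse"` or `"fine"`.
#' @return List with numeric vectors `log2c` and `log2gamma`.
#' @export
log2_grid <- function(resolution = c("coarse", "fine")) {
  resolution <- match.arg(resolution)
  step <- if (resolution == "fine") 0.2 else 2
  list(log2c = seq(-5, 15, by = step), log2gamma = seq(-15, 8, by = step))
}

#' Train an RBF-kernel SVM on a labeled feature matrix
#'
#' Thin wrapper over libsvm (via e1071) fixing the package conventions:
#' RBF kernel, no rescaling of the frequency features (already in \[0, 1\]),
#' and a decision-score sign convention where positive scores predict the
#' positive (enzyme) class.
#'
#' @param features Labeled feature tibble (both classes present, no
#'   missing values).
#' @param config An [svm_config()].
#' @param scale Standardize features before training? Off by default.
#' @return An object of class `enzid_svm`: the fitted model plus the
#'   feature column order and config, so prediction is self-contained.
#' @export
svm_train <- function(features, config = svm_config(), scale = FALSE) {
  stopifnot(inherits(config, "enzid_svm_config"),
            "label" %in% names(features))
  cols <- feature_names(features)
  x <- as.matrix(features[, cols])
  y <- droplevels(factor(features$label, levels = c("positive", "negative")))
  if (nlevels(y) < 2) {
    stop("training data contains a single class; need both positive and ",
         "negative examples", call. = FALSE)
  }
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  gamma <- config$gamma %||% (1 / ncol(x))
  fit <- e1071::svm(x, y, kernel = "radial", cost = config$cost,
                    gamma = gamma, scale = scale)
  structure(list(fit = fit, columns = cols, config = config, scale = scale),
            class = "enzid_svm")
}

# Predict labels and signed decision scores (positive score -> "positive").
.svm_predict <- function(model, features) {
  x <- as.matrix(features[, model$columns])
  pr <- stats::predict(model$fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  score <- dv[, 1]
  # libsvm orients the score toward whichever class it saw first; the
  # column name "<first>/<second>" says which. Normalize to positive class.
  if (!startsWith(colnames(dv)[1], "positive")) score <- -score
  tibble::tibble(id = features$id,
                 label = factor(as.character(pr),
                                levels = c("positive", "negative")),
                 score = unname(score))
}

#' Predict labels for new sequences or features
#'
#' @param object An `enzid_svm` model from [svm_train()].
#' @param newdata A feature tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Tibble with `id`, predicted `label` and decision `score`
#'   (positive score predicts the positive/enzyme class).
#' @export
predict.enzid_svm <- function(object, newdata, ...) {
  .svm_predict(object, newdata)
}

#' Assign cross-validation folds
#'
#' Random fold assignment, optionally stratified by class so each fold has
#' near-identical class balance. Fully determined by `seed`.
#'
#' @param labels Factor of class labels (one per sample).
#' @param n_folds Number of folds (>= 2, <= number of samples; when
#'   stratified, <= the smaller class size).
#' @param seed Integer seed.
#' @param stratified Stratify by class?
#' @return Integer vector of fold ids in 1..n_folds, one per sample.
#' @export
make_folds <- function(labels, n_folds, seed = 1, stratified = TRUE) {
  n <- length(labels)
  if (n_folds < 2 || n_folds > n) {
    stop("n_folds must be between 2 and the sample count (", n, ")",
         call. = FALSE)
  }
  if (stratified && n_folds > min(table(labels))) {
    stop("stratified folds require n_folds <= smaller class size (",
         min(table(labels)), ")", call. = FALSE)
  }
  rng <- .new_rng(seed)
  folds <- integer(n)
  if (stratified) {
    for (cls in levels(factor(labels))) {
      idx <- which(labels == cls)
      folds[idx[.rng_sample(rng, length(idx))]] <-
        rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    folds[.rng_sample(rng, n)] <- rep_len(seq_len(n_folds), n)
  }
  folds
}

# Local RNG: seeded sampling that never disturbs the global .Random.seed.
.new_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  env
}

.with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

.rng_sample <- function(rng, n, ...) .with_rng(rng, sample.int(n, ...))
.rng_runif <- function(rng, n) .with_rng(rng, stats::runif(n))

#' k-fold cross-validation of an RBF-SVM
#'
#' Partitions the samples into `n_folds` random (optionally stratified)
#' folds; each fold is held out once while the model trains on the rest.
#' Per-fold confusion matrices are pooled into aggregate counts, and
#' decision scores for every held-out sample are retained for ROC analysis.
#' The `n_folds = n` limit is leave-one-out (jackknife) validation.
#'
#' @inheritParams svm_train
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for fold assignment.
#' @param stratified Stratify folds by class?
#' @return An object of class `enzid_cv`: per-fold confusion tibble,
#'   pooled [confusion_matrix()], pooled metrics, and an out-of-fold
#'   predictions tibble (`id`, `fold`, `truth`, `pred`, `score`). Use
#'   [generics::tidy()] for per-fold metrics and [generics::glance()] for
#'   the pooled row.
#' @export
cross_validate <- function(features, config = svm_config(), n_folds = 6,
                           seed = 1, stratified = TRUE, scale = FALSE) {
  stopifnot("label" %in% names(features))
  labels <- factor(features$label, levels = c("positive", "negative"))
  folds <- make_folds(labels, n_folds, seed, stratified)
  truth <- list(); pred <- list(); score <- list(); fold_id <- list()
  for (f in seq_len(n_folds)) {
    tr <- features[folds != f, ]
    te <- features[folds == f, ]
    fit <- svm_train(tr, config, scale = scale)
    pr <- .svm_predict(fit, te)
    truth[[f]] <- labels[folds == f]
    pred[[f]] <- pr$label
    score[[f]] <- pr$score
    fold_id[[f]] <- rep(f, nrow(te))
  }
  out <- .assemble_cv(truth, pred, score, fold_id, n_folds, seed, config)
  out$predictions$id <- features$id[order(folds, method = "radix")]
  out
}

.assemble_cv <- function(truth, pred, score, fold_id, n_folds, seed, config) {
  fold_cm <- purrr::map2(truth, pred, confusion_matrix)
  per_fold <- dplyr::bind_rows(purrr::imap(fold_cm, function(cm, f) {
    tibble::tibble(fold = as.integer(f), tp = cm$tp, tn = cm$tn,
                   fp = cm$fp, fn = cm$fn)
  }))
  pooled <- confusion_matrix(
    factor(unlist(lapply(truth, as.character)),
           levels = c("positive", "negative")),
    factor(unlist(lapply(pred, as.character)),
           levels = c("positive", "negative")))
  predictions <- tibble::tibble(
    id = NA_character_,
    fold = unlist(fold_id),
    truth = factor(unlist(lapply(truth, as.character)),
                   levels = c("positive", "negative")),
    pred = factor(unlist(lapply(pred, as.character)),
                  levels = c("positive", "negative")),
    score = unlist(score))
  structure(list(folds = per_fold, pooled = pooled,
                 metrics = suppressWarnings(metrics(pooled)),
                 predictions = predictions,
                 n_folds = n_folds, seed = seed, config = config),
            class = "enzid_cv")
}

#' @export
print.enzid_cv <- function(x, ...) {
  g <- x$metrics
  cat(x$n_folds, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  pooled ACC: %.2f%%  SP(paper): %.4f  SE(paper): %.4f\n",
              g$acc, g$sp_paper, g$se_paper))
  cat("  pooled confusion: TP=", x$pooled$tp, " TN=", x$pooled$tn,
      " FP=", x$pooled$fp, " FN=", x$pooled$fn, "\n", sep = "")
  invisible(x)
}

#' Grid search over RBF-SVM hyperparameters
#'
#' Evaluates c = 2^a, gamma = 2^b for every pair (a, b) on the supplied
#' exponent grids by [cross_validate()] with a fixed fold assignment
#' (same seed for every point), and returns the configuration maximizing
#' pooled cross-validated accuracy. Ties go to the smaller a, then the
#' smaller b.
#'
#' @inheritParams cross_validate
#' @param log2c,log2gamma Numeric vectors of exponents a and b.
#' @return An object of class `enzid_grid`: `best_config` ([svm_config()]),
#'   `best` (its grid row) and `grid` (tibble log2c / log2gamma / cost /
#'   gamma / acc / sp_paper / se_paper).
#' @export
#' @examples
#' \donttest{
#' d <- simulate_enzyme_dataset(n_pos = 20, n_neg = 20, seed = 7)
#' f <- encode_features(d, k = 3, descriptors = informative_pairs_k3())
#' grid_search(f, log2c = c(0, 5), log2gamma = c(-5, 0), n_folds = 4)
#' }
grid_search <- function(features, log2c, log2gamma, n_folds = 6, seed = 1,
                        stratified = TRUE, scale = FALSE) {
  stopifnot(length(log2c) > 0, length(log2gamma) > 0)
  pts <- expand.grid(log2gamma = log2gamma, log2c = log2c,
                     KEEP.OUT.ATTRS = FALSE)[, c("log2c", "log2gamma")]
  rows <- purrr::pmap(pts, function(log2c, log2gamma) {
    cfg <- svm_config(cost = 2^log2c, gamma = 2^log2gamma)
    cv <- cross_validate(features, config = cfg, n_folds = n_folds,
                         seed = seed, stratified = stratified, scale = scale)
    g <- cv$metrics
    tibble::tibble(log2c = log2c, log2gamma = log2gamma,
                   cost = 2^log2c, gamma = 2^log2gamma,
                   acc = g$acc, sp_paper = g$sp_paper, se_paper = g$se_paper)
  })
  grid <- dplyr::bind_rows(rows)
  ord <- order(-grid$acc, grid$log2c, grid$log2gamma)
  best <- grid[ord[1], ]
  structure(list(
    best_config = svm_config(cost = best$cost, gamma = best$gamma),
    best = best, grid = grid, n_folds = n_folds, seed = seed
  ), class = "enzid_grid")
}

#' @export
print.enzid_grid <- function(x, ...) {
  cat("RBF-SVM grid search (", nrow(x$grid), " points, ", x$n_folds,
      "-fold CV)\n", sep = "")
  cat(sprintf("  best: c = 2^%.1f = %.4f, gamma = 2^%.1f = %.4f, ACC = %.2f%%\n",
              x$best$log2c, x$best$cost, x$best$log2gamma, x$best$gamma,
              x$best$acc))
  invisible(x)
}
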