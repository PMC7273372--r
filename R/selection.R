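#' Two-group ANOVA F statistic per feature
#'
#' For each feature column, computes the one-way ANOVA F statistic between
#' the two label groups: F = MSB / MSW, where with g = 2 groups of sizes
#' n1, n2 (n = n1 + n2), group means x1, x2 and grand mean x,
#' MSB = \[n1 (x1 - x)^2 + n2 (x2 - x)^2\] / (g - 1) and MSW is the pooled
#' within-group sum of squared deviations divided by (n - g). For two
#' groups F equals the square of the pooled-variance two-sample t statistic.
#'
#' Degenerate cases: a column with some between-group difference but zero
#' within-group variance gets `F = Inf` (a perfectly separating feature);
#' a constant column gets `F = 0` (no information).
#'
#' @param features A labeled feature tibble from [encode_features()] (must
#'   have a `label` column with both classes present, each with at least
#'   2 samples).
#' @return A tibble with one row per feature: `descriptor`, `msb`, `msw`,
#'   `F`.
#' @export
#' @examples
#' x <- tibble::tibble(id = as.character(1:6),
#'                     label = factor(rep(c("positive", "negative"), each = 3),
#'                                    levels = c("positive", "negative")),
#'                     f1 = c(1, 2, 3, 4, 5, 6))
#' anova_f(x)  # F = 13.5
anova_f <- function(features) {
  stopifnot("label" %in% names(features))
  lab <- features$label
  grp <- lab == "positive"
  n1 <- sum(grp); n2 <- sum(!grp); n <- n1 + n2
  if (n1 < 2 || n2 < 2) {
    stop("each class needs at least 2 samples (got ", n1, " positive, ",
         n2, " negative)", call. = FALSE)
  }
  cols <- feature_names(features)
  x <- as.matrix(features[, cols])
  m1 <- colMeans(x[grp, , drop = FALSE])
  m2 <- colMeans(x[!grp, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  msb <- (n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2) / 1
  ssw <- colSums(sweep(x[grp, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(x[!grp, , drop = FALSE], 2, m2)^2)
  msw <- ssw / (n - 2)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  tibble::tibble(descriptor = cols, msb = unname(msb), msw = unname(msw),
                 F = unname(f))
}

#' Rank features by descending F statistic
#'
#' Orders an F-score table by descending F. Infinite F (perfect separators)
#' sorts first; ties are broken by ascending descriptor name so the ranking
#' is fully deterministic.
#'
#' @param fscores A tibble from [anova_f()].
#' @return The table sorted, with an added `rank` column.
#' @export
rank_features <- function(fscores) {
  stopifnot(all(c("descriptor", "F") %in% names(fscores)))
  ord <- order(-fscores$F, fscores$descriptor)
  out <- fscores[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Incremental forward selection of k-spaced pairs over an AAC base
#'
#' The three-step selection procedure: (1) rank all 400 CKSAAP(k) pairs by
#' their two-group ANOVA F statistic; (2) for each subset size m = 1 ...
#' `max_m`, form the feature set AAC block + top-m ranked pairs; (3) score
#' each subset by k-fold cross-validated SVM accuracy. Returns the full
#' accuracy curve and the best m (ties broken toward the smaller, more
#' parsimonious subset).
#'
#' By default ranking is computed once on the full supplied dataset, which
#' mirrors the published protocol but lets selection see the validation
#' folds; `fold_safe = TRUE` instead re-ranks within each training fold so
#' the accuracy curve is free of selection leakage.
#'
#' By default the SVM hyperparameters are re-tuned for every subset size via
#' [grid_search()] on `grid`; pass a single [svm_config()] as `config` to
#' use fixed hyperparameters instead (much faster).
#'
#' @param sequences Labeled sequence tibble (from [load_labeled_dataset()]
#'   or [simulate_enzyme_dataset()]), or an already-encoded labeled feature
#'   tibble containing an AAC block plus a single CKSAAP block at gap `k`.
#' @param k CKSAAP gap size to select over.
#' @param max_m Largest number of pairs to add (<= 400).
#' @param n_folds Cross-validation folds.
#' @param seed Integer seed controlling fold assignment.
#' @param grid A list with `log2c` and `log2gamma` numeric vectors (see
#'   [log2_grid()]); used when `config` is NULL.
#' @param config Optional fixed [svm_config()]; skips per-m tuning.
#' @param convention CKSAAP denominator convention.
#' @param fold_safe Re-rank features inside each training fold?
#' @param stratified Stratify CV folds by class?
#' @return An object of class `enzid_selection`: list with `ranking` (the
#'   ranked F-score table), `curve` (tibble m / acc / sp_paper / se_paper),
#'   `best_m`, `best_features` (AAC letters + top-m pair names), `k`,
#'   and the per-m tuned configs when tuning was used.
#' @export
select_incremental <- function(sequences, k = 3, max_m = 30, n_folds = 6,
                               seed = 1, grid = log2_grid("coarse"),
                               config = NULL,
                               convention = c("paper", "pair-count"),
                               fold_safe = FALSE, stratified = TRUE) {
  convention <- match.arg(convention)
  stopifnot(max_m >= 1, max_m <= 400)
  feats <- .selection_features(sequences, k, convention)
  aac_cols <- intersect(amino_acids(), names(feats))
  pair_cols <- setdiff(feature_names(feats), aac_cols)

  ranking <- rank_features(anova_f(feats[, c("id", "label", pair_cols)]))
  curve <- vector("list", max_m)
  configs <- vector("list", max_m)
  for (m in seq_len(max_m)) {
    cols <- c(aac_cols, ranking$descriptor[seq_len(m)])
    sub <- feats[, c("id", "label", cols)]
    if (fold_safe) {
      cv <- .cv_fold_safe(feats, aac_cols, pair_cols, m,
                          config = config %||% svm_config(),
                          n_folds = n_folds, seed = seed,
                          stratified = stratified)
      configs[[m]] <- config %||% svm_config()
    } else if (is.null(config)) {
      gs <- grid_search(sub, log2c = grid$log2c, log2gamma = grid$log2gamma,
                        n_folds = n_folds, seed = seed,
                        stratified = stratified)
      configs[[m]] <- gs$best_config
      cv <- cross_validate(sub, config = gs$best_config, n_folds = n_folds,
                           seed = seed, stratified = stratified)
    } else {
      configs[[m]] <- config
      cv <- cross_validate(sub, config = config, n_folds = n_folds,
                           seed = seed, stratified = stratified)
    }
    g <- glance(cv)
    curve[[m]] <- tibble::tibble(m = m, acc = g$acc, sp_paper = g$sp_paper,
                                 se_paper = g$se_paper)
  }
  curve <- dplyr::bind_rows(curve)
  best_m <- curve$m[which.max(curve$acc)]  # which.max takes the first max
  structure(list(
    ranking = ranking,
    curve = curve,
    best_m = best_m,
    best_features = c(aac_cols, ranking$descriptor[seq_len(best_m)]),
    best_config = configs[[best_m]],
    configs = configs,
    k = k, n_folds = n_folds, seed = seed, fold_safe = fold_safe
  ), class = "enzid_selection")
}

# Accept raw sequences or a pre-encoded matrix.
.selection_features <- function(sequences, k, convention) {
  if ("residues" %in% names(sequences)) {
    encode_features(sequences, aac = TRUE, k = k, convention = convention)
  } else {
    stopifnot("label" %in% names(sequences))
    sequences
  }
}

# Fold-safe scoring: rank pairs on each training fold only.
.cv_fold_safe <- function(feats, aac_cols, pair_cols, m, config,
                          n_folds, seed, stratified) {
  folds <- make_folds(feats$label, n_folds, seed, stratified)
  truth <- list(); pred <- list(); score <- list(); fold_id <- list()
  for (f in seq_len(n_folds)) {
    tr <- feats[folds != f, ]
    te <- feats[folds == f, ]
    rk <- rank_features(anova_f(tr[, c("id", "label", pair_cols)]))
    cols <- c(aac_cols, rk$descriptor[seq_len(m)])
    fit <- svm_train(tr[, c("id", "label", cols)], config)
    pr <- .svm_predict(fit, te[, c("id", cols)])
    truth[[f]] <- te$label; pred[[f]] <- pr$label; score[[f]] <- pr$score
    fold_id[[f]] <- rep(f, nrow(te))
  }
  .assemble_cv(truth, pred, score, fold_id, n_folds, seed, config)
}

#' @export
print.enzid_selection <- function(x, ...) {
  cat("Incremental CKSAAP(k=", x$k, ") selection over AAC\n", sep = "")
  cat("  subset sizes scored: 1..", max(x$curve$m), " (", x$n_folds,
      "-fold CV)\n", sep = "")
  cat("  best m: ", x$best_m, "  CV accuracy: ",
      sprintf("%.2f%%", x$curve$acc[x$curve$m == x$best_m]), "\n", sep = "")
  cat("  top pairs: ",
      paste(utils::head(x$ranking$descriptor, min(5, x$best_m)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write selection outputs to plain-text files
#'
#' Writes the ranked F-score table and the accuracy curve as TSV, and the
#' best feature subset as a one-descriptor-per-line text file that can be
#' fed back to [encode_features()] via `descriptors = readLines(...)`.
#'
#' @param selection An `enzid_selection` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_selection <- function(selection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ranking = file.path(dir, "fscore_ranking.tsv"),
    curve = file.path(dir, "selection_curve.tsv"),
    features = file.path(dir, "best_features.txt")
  )
  readr::write_tsv(selection$ranking, paths["ranking"])
  readr::write_tsv(selection$curve, paths["curve"])
  writeLines(selection$best_features, paths["features"])
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
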