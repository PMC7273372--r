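#' Full enzyme-identification pipeline
#'
#' Runs the complete workflow on a labeled sequence dataset:
#'
#' 1. encode AAC + CKSAAP(k) features;
#' 2. rank the 400 pairs by two-group ANOVA F statistic;
#' 3. incremental forward selection of the top-m pairs over the AAC base,
#'    each subset scored by k-fold cross-validated SVM accuracy;
#' 4. grid search of (c, gamma) on the selected subset;
#' 5. final cross-validation of the tuned model, with pooled
#'    confusion-matrix metrics and a ROC curve from the out-of-fold
#'    decision scores;
#' 6. a final model trained on all data, carrying its encoding spec so it
#'    can predict directly on new FASTA input.
#'
#' All randomness (fold assignments) derives from `seed`.
#'
#' @param sequences Labeled sequence tibble from [load_labeled_dataset()]
#'   or [simulate_enzyme_dataset()].
#' @param k CKSAAP gap size (default 3, the configuration that performs
#'   best on the human-enzyme task).
#' @param max_m Largest pair-subset size scored during selection.
#' @param n_folds Cross-validation folds (default 6).
#' @param seed Integer seed.
#' @param grid Exponent grid for tuning, see [log2_grid()].
#' @param tune_per_m Re-tune (c, gamma) for every subset size during
#'   selection (default), or tune once after selection with subsets scored
#'   at `fixed_config`.
#' @param fixed_config [svm_config()] used during selection when
#'   `tune_per_m = FALSE`.
#' @param convention CKSAAP denominator convention.
#' @param fold_safe Re-rank features inside CV training folds during
#'   selection (leakage-free mode).
#' @param stratified Stratify CV folds by class?
#' @return An object of class `enzid_fit` with elements `selection`
#'   (`enzid_selection`), `tuning` (`enzid_grid`), `cv` (`enzid_cv`),
#'   `roc` (`enzid_roc`), `model` (`enzid_svm` on all data), `spec`
#'   (encoding spec of the selected features) and the call parameters.
#' @export
#' @examples
#' \donttest{
#' d <- simulate_enzyme_dataset(n_pos = 30, n_neg = 30, seed = 11)
#' fit <- run_pipeline(d, max_m = 3, n_folds = 3,
#'                     grid = list(log2c = c(0, 4), log2gamma = c(-4, 0)))
#' glance(fit)
#' }
run_pipeline <- function(sequences, k = 3, max_m = 30, n_folds = 6,
                         seed = 1, grid = log2_grid("coarse"),
                         tune_per_m = TRUE, fixed_config = svm_config(),
                         convention = c("paper", "pair-count"),
                         fold_safe = FALSE, stratified = TRUE) {
  convention <- match.arg(convention)
  stopifnot("label" %in% names(sequences),
            all(c("positive", "negative") %in% sequences$label))
  message("pipeline: encoding AAC + CKSAAP(k=", k, ") for ",
          nrow(sequences), " sequences")
  sel <- select_incremental(
    sequences, k = k, max_m = max_m, n_folds = n_folds, seed = seed,
    grid = grid, config = if (tune_per_m) NULL else fixed_config,
    convention = convention, fold_safe = fold_safe, stratified = stratified)
  message("pipeline: selection done, best m = ", sel$best_m)
  feats <- encode_features(sequences, aac = TRUE, convention = convention,
                           descriptors = sel$best_features)
  tuning <- grid_search(feats, log2c = grid$log2c,
                        log2gamma = grid$log2gamma, n_folds = n_folds,
                        seed = seed, stratified = stratified)
  message(sprintf("pipeline: tuned c = %.4f, gamma = %.4f",
                  tuning$best_config$cost, tuning$best_config$gamma))
  cv <- cross_validate(feats, config = tuning$best_config,
                       n_folds = n_folds, seed = seed,
                       stratified = stratified)
  roc <- roc_curve(cv$predictions$truth, cv$predictions$score)
  model <- svm_train(feats, tuning$best_config)
  spec <- encoding_spec(aac = TRUE, convention = convention,
                        descriptors = sel$best_features)
  structure(list(selection = sel, tuning = tuning, cv = cv, roc = roc,
                 model = model, spec = spec,
                 params = list(k = k, max_m = max_m, n_folds = n_folds,
                               seed = seed, tune_per_m = tune_per_m,
                               convention = convention,
                               fold_safe = fold_safe,
                               stratified = stratified)),
            class = "enzid_fit")
}

#' @export
print.enzid_fit <- function(x, ...) {
  g <- x$cv$metrics
  cat("Enzyme-identification fit\n")
  cat("  features: 20 AAC + ", x$selection$best_m, " CKSAAP(k=",
      x$params$k, ") pairs\n", sep = "")
  cat(sprintf("  tuned: c = %.4f, gamma = %.4f\n",
              x$tuning$best_config$cost, x$tuning$best_config$gamma))
  cat(sprintf("  %d-fold CV: ACC = %.2f%%, SP(paper) = %.4f, SE(paper) = %.4f, AUC = %.4f\n",
              x$params$n_folds, g$acc, g$sp_paper, g$se_paper, x$roc$auc))
  invisible(x)
}

#' Predict enzyme labels for new sequences with a fitted pipeline
#'
#' Applies the stored encoding spec and tuned SVM to new sequences; no
#' feature specification is required. Sequences that cannot be encoded
#' (non-standard residues, or too short for the spec's gap sizes) get an
#' error row (`label`/`score` NA, `note` holding the message) and the run
#' continues.
#'
#' @param object An `enzid_fit` from [run_pipeline()] or a loaded model
#'   from [read_model()].
#' @param newdata Sequence tibble (`id`, `residues`) or path to a FASTA
#'   file.
#' @param ... Unused.
#' @return Tibble with `id`, predicted `label`, decision `score`, `note`.
#' @export
predict.enzid_fit <- function(object, newdata, ...) {
  .predict_with_spec(object$model, object$spec, newdata)
}

.predict_with_spec <- function(model, spec, newdata) {
  if (is.character(newdata) && length(newdata) == 1 &&
      file.exists(newdata)) {
    newdata <- read_fasta(newdata)
  }
  newdata <- .as_sequence_tbl(newdata)
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    one <- newdata[i, ]
    res <- tryCatch({
      f <- .encode_with_spec(one, spec)
      pr <- .svm_predict(model, f)
      tibble::tibble(id = one$id, label = as.character(pr$label),
                     score = pr$score, note = NA_character_)
    }, error = function(e) {
      tibble::tibble(id = one$id, label = NA_character_,
                     score = NA_real_, note = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  out$label <- factor(out$label, levels = c("positive", "negative"))
  out
}

#' Save / load a fitted model with its encoding spec
#'
#' Serializes the tuned SVM together with the encoding specification
#' (selected descriptors, gap sizes, denominator convention) so that
#' prediction on a new FASTA file is fully self-contained.
#'
#' @param fit An `enzid_fit` (or a list with `model` and `spec`).
#' @param path Output file path (RDS).
#' @return `path` invisibly; `read_model()` returns a list of class
#'   `enzid_model_file` with `model` and `spec`, usable with [predict()].
#' @export
write_model <- function(fit, path) {
  stopifnot(!is.null(fit$model), !is.null(fit$spec))
  saveRDS(list(model = fit$model, spec = fit$spec,
               package_version = as.character(utils::packageVersion("enzid"))),
          path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(!is.null(obj$model), !is.null(obj$spec))
  structure(obj, class = "enzid_model_file")
}

#' @export
predict.enzid_model_file <- function(object, newdata, ...) {
  .predict_with_spec(object$model, object$spec, newdata)
}

#' Write pipeline outputs to a directory
#'
#' Emits the selection curve and ranking (TSV), the best-feature list,
#' the tuning grid (TSV), pooled metrics (JSON), ROC points (TSV) and the
#' serialized model.
#'
#' @param fit An `enzid_fit`.
#' @param dir Output directory (created if needed).
#' @return Named vector of paths, invisibly.
#' @export
write_pipeline <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sel_paths <- write_selection(fit$selection, dir)
  paths <- c(sel_paths,
             grid = file.path(dir, "tuning_grid.tsv"),
             metrics = file.path(dir, "metrics.json"),
             roc = file.path(dir, "roc.tsv"),
             model = file.path(dir, "model.rds"))
  readr::write_tsv(fit$tuning$grid, paths["grid"])
  m <- fit$cv$metrics
  m$auc <- fit$roc$auc
  m$best_m <- fit$selection$best_m
  m$cost <- fit$tuning$best_config$cost
  m$gamma <- fit$tuning$best_config$gamma
  m$seed <- fit$params$seed
  write_metrics(m, paths["metrics"])
  write_roc(fit$roc, paths["roc"])
  write_model(fit, paths["model"])
  invisible(paths)
}
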