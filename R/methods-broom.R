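#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy/glance methods for cross-validation results
#'
#' `tidy()` returns one row per fold with its confusion counts and metrics;
#' `glance()` returns the single pooled row.
#'
#' @param x An `enzid_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy enzid_cv
#' @export
tidy.enzid_cv <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(nrow(x$folds)), function(i) {
    r <- x$folds[i, ]
    cm <- structure(list(tp = r$tp, tn = r$tn, fp = r$fp, fn = r$fn),
                    class = "enzid_confusion")
    dplyr::bind_cols(tibble::tibble(fold = r$fold),
                     suppressWarnings(metrics(cm)))
  }))
}

#' @rdname tidy.enzid_cv
#' @method glance enzid_cv
#' @export
glance.enzid_cv <- function(x, ...) x$metrics

#' Tidy/glance methods for selection results
#'
#' `tidy()` returns the per-subset-size accuracy curve; `glance()` the
#' best subset's row plus its size.
#'
#' @param x An `enzid_selection` from [select_incremental()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy enzid_selection
#' @export
tidy.enzid_selection <- function(x, ...) x$curve

#' @rdname tidy.enzid_selection
#' @method glance enzid_selection
#' @export
glance.enzid_selection <- function(x, ...) {
  best <- x$curve[x$curve$m == x$best_m, ]
  dplyr::bind_cols(tibble::tibble(best_m = x$best_m),
                   best[, setdiff(names(best), "m")])
}

#' Tidy/glance methods for grid-search results
#'
#' `tidy()` returns the full (log2c, log2gamma) accuracy surface;
#' `glance()` the winning row.
#'
#' @param x An `enzid_grid` from [grid_search()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy enzid_grid
#' @export
tidy.enzid_grid <- function(x, ...) x$grid

#' @rdname tidy.enzid_grid
#' @method glance enzid_grid
#' @export
glance.enzid_grid <- function(x, ...) x$best

#' Tidy method for ROC curves
#'
#' @param x An `enzid_roc` from [roc_curve()].
#' @param ... Unused.
#' @return The (threshold, fpr, tpr) points tibble.
#' @method tidy enzid_roc
#' @export
tidy.enzid_roc <- function(x, ...) x$points

#' @rdname tidy.enzid_roc
#' @method glance enzid_roc
#' @export
glance.enzid_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy/glance methods for full pipeline fits
#'
#' `tidy()` returns the selection curve; `glance()` a one-row summary of
#' the final model (subset size, tuned hyperparameters, pooled CV metrics,
#' AUC).
#'
#' @param x An `enzid_fit` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy enzid_fit
#' @export
tidy.enzid_fit <- function(x, ...) x$selection$curve

#' @rdname tidy.enzid_fit
#' @method glance enzid_fit
#' @export
glance.enzid_fit <- function(x, ...) {
  g <- x$cv$metrics
  tibble::tibble(
    best_m = x$selection$best_m,
    cost = x$tuning$best_config$cost,
    gamma = x$tuning$best_config$gamma,
    acc = g$acc, sp_paper = g$sp_paper, se_paper = g$se_paper,
    auc = x$roc$auc
  )
}
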