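#' Confusion matrix for binary enzyme classification
#'
#' Cross-classifies true against predicted labels. The positive class is
#' "enzyme"; TP counts enzymes predicted as enzymes, TN non-enzymes
#' predicted as non-enzymes, FP non-enzymes predicted as enzymes, FN
#' enzymes predicted as non-enzymes.
#'
#' @param truth,pred Equal-length vectors/factors of labels in
#'   {"positive", "negative"}.
#' @return A list of class `enzid_confusion` with integer fields `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
#' @examples
#' confusion_matrix(c("positive", "negative"), c("positive", "positive"))
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("truth and pred have different lengths (", length(truth), " vs ",
         length(pred), ")", call. = FALSE)
  }
  lv <- c("positive", "negative")
  truth <- factor(as.character(truth), levels = lv)
  pred <- factor(as.character(pred), levels = lv)
  if (anyNA(truth) || anyNA(pred)) {
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  }
  structure(list(
    tp = sum(truth == "positive" & pred == "positive"),
    tn = sum(truth == "negative" & pred == "negative"),
    fp = sum(truth == "negative" & pred == "positive"),
    fn = sum(truth == "positive" & pred == "negative")
  ), class = "enzid_confusion")
}

#' @export
print.enzid_confusion <- function(x, ...) {
  cat("Confusion: TP=", x$tp, " TN=", x$tn, " FP=", x$fp, " FN=", x$fn,
      "\n", sep = "")
  invisible(x)
}

#' Classification metrics (ACC, SP, SE) from a confusion matrix
#'
#' Computes accuracy and the two class-conditional rates using the naming
#' convention of the human-enzyme identification literature this package
#' follows, in which **SP = TP/(TP+FN)** (the rate on positives) and
#' **SE = TN/(TN+FP)** (the rate on negatives) — the reverse of common
#' usage. Both are reported under those names (`sp_paper`, `se_paper`) and
#' under the standard names (`sensitivity` = `sp_paper`, `specificity` =
#' `se_paper`) so no reader is misled. A ratio with a zero denominator is
#' `NA` (with a warning), never coerced to 0 or 1.
#'
#' @param cm An `enzid_confusion` from [confusion_matrix()].
#' @return One-row tibble: `acc` (percentage in \[0, 100\]), `sp_paper`,
#'   `se_paper`, `sensitivity`, `specificity` (ratios in \[0, 1\]), and the
#'   four counts.
#' @export
#' @examples
#' metrics(confusion_matrix(rep(c("positive", "negative"), c(4, 6)),
#'                          rep(c("positive", "negative"), c(4, 6))))
metrics <- function(cm) {
  stopifnot(inherits(cm, "enzid_confusion"))
  n <- cm$tp + cm$tn + cm$fp + cm$fn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sp <- ratio(cm$tp, cm$tp + cm$fn, "SP (rate on positives)")
  se <- ratio(cm$tn, cm$tn + cm$fp, "SE (rate on negatives)")
  tibble::tibble(
    acc = 100 * (cm$tp + cm$tn) / n,
    sp_paper = sp, se_paper = se,
    sensitivity = sp, specificity = se,
    tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn
  )
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps a decision threshold over the unique scores in descending order
#' (samples with tied scores enter together, advancing the curve
#' diagonally in one step), producing (FPR, TPR) points from (0, 0) to
#' (1, 1). The AUC is the trapezoidal area under those points, equal to
#' the probability that a random positive outscores a random negative
#' (ties counted 1/2).
#'
#' @param truth Labels in {"positive", "negative"}; both classes required.
#' @param score Numeric decision scores, larger = more enzyme-like.
#' @return An object of class `enzid_roc`: `points` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
#' @examples
#' roc_curve(c("positive", "positive", "negative"), c(2.0, 1.5, -1.0))$auc
roc_curve <- function(truth, score) {
  if (length(truth) != length(score)) {
    stop("truth and score have different lengths", call. = FALSE)
  }
  pos <- as.character(truth) == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]
  last <- !duplicated(s, fromLast = TRUE)  # group tied scores
  tpr <- cumsum(p)[last] / n_pos
  fpr <- cumsum(!p)[last] / n_neg
  pts <- tibble::tibble(threshold = c(Inf, s[last]),
                        fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "enzid_roc")
}

#' @export
print.enzid_roc <- function(x, ...) {
  cat("ROC curve: ", nrow(x$points) - 1, " thresholds, AUC = ",
      sprintf("%.4f", x$auc), "\n", sep = "")
  invisible(x)
}

#' Write a metrics row / ROC points to disk
#'
#' Metrics go to JSON (and TSV alongside); ROC points to two-column TSV.
#'
#' @param x A [metrics()] row or an `enzid_roc`.
#' @param path Output path (JSON for metrics, TSV for ROC).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_roc <- function(x, path) {
  stopifnot(inherits(x, "enzid_roc"))
  readr::write_tsv(x$points[, c("fpr", "tpr")], path)
  invisible(path)
}
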