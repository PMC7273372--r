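# Independent brute-force oracles and tiny fixture builders. These
# deliberately avoid the package's vectorized code paths: encoders are
# checked against per-position loops, ANOVA F against t.test, AUC against
# the pair-counting rank statistic.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(L, alphabet = AA20) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# AAC oracle: explicit per-character tally.
oracle_aac <- function(s) {
  ch <- strsplit(s, "")[[1]]
  counts <- setNames(numeric(20), AA20)
  for (c in ch) counts[c] <- counts[c] + 1
  counts / nchar(s)
}

# CKSAAP oracle: explicit sliding-window position loop.
oracle_cksaap <- function(s, k, convention = "paper") {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  counts <- numeric(400)
  for (p in seq_len(L - k - 1)) {
    i <- match(ch[p], AA20)
    j <- match(ch[p + k + 1], AA20)
    counts[(i - 1) * 20 + j] <- counts[(i - 1) * 20 + j] + 1
  }
  denom <- if (convention == "paper") L - k else L - k - 1
  counts / denom
}

# Two-group F oracle: squared pooled-variance two-sample t statistic.
oracle_f_from_t <- function(x1, x2) {
  tt <- t.test(x1, x2, var.equal = TRUE)
  unname(tt$statistic^2)
}

# AUC oracle: fraction of positive-negative pairs correctly ordered,
# ties counted 1/2.
oracle_auc <- function(truth, score) {
  pos <- score[truth == "positive"]
  neg <- score[truth == "negative"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# A labeled feature tibble from a plain matrix.
as_feature_tbl <- function(x, labels) {
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  dplyr::bind_cols(
    tibble::tibble(id = paste0("s", seq_len(nrow(x))),
                   label = factor(labels, levels = c("positive", "negative"))),
    tibble::as_tibble(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two well-separated Gaussian clouds in 2-D.
separable_features <- function(n_per_class = 20, gap = 6, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = gap), ncol = 2))
  as_feature_tbl(x, rep(c("positive", "negative"), each = n_per_class))
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
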