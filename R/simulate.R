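#' Default enriched-pair specification
#'
#' The generator's default class signal: the pairs (A, A) and (L, L) at gap
#' k = 3, each overwritten into positive-class sequences at rate 0.15 per
#' eligible start position. These are homopairs known to carry signal in
#' the human-enzyme task (see [informative_pairs_k3()]).
#'
#' @return Tibble with columns `res1`, `res2`, `k`, `rate`.
#' @export
default_enriched_pairs <- function() {
  tibble::tibble(res1 = c("A", "L"), res2 = c("A", "L"),
                 k = c(3L, 3L), rate = c(0.15, 0.15))
}

#' Simulate a two-class protein sequence dataset
#'
#' Generates a labeled dataset emulating the shape of a curated
#' enzyme/non-enzyme sequence collection: two classes of variable-length
#' sequences with residues drawn independently from a background
#' distribution. Positive-class sequences additionally carry enriched
#' k-spaced residue pairs: for each enriched pair and each eligible start
#' position p (1 ... L - k - 1), with probability `rate` the pair's
#' residues overwrite positions p and p + k + 1. Overwriting (rather than
#' inserting) keeps lengths fixed and the background composition nearly
#' intact, so the planted signal is specifically a k-spaced pair signal.
#'
#' All randomness flows from `seed` through one stream; the same
#' configuration and seed always reproduce the same dataset. The planted
#' descriptors are attached as the `ground_truth` attribute for recovery
#' tests.
#'
#' @param n_pos,n_neg Class sizes (positives = enzymes).
#' @param length_range Integer (min, max) sequence length; lengths are
#'   drawn uniformly. Minimum must be >= max(k) + 2.
#' @param background Length-20 residue probability vector in the order of
#'   [amino_acids()]; must sum to 1. Default uniform (0.05 each).
#' @param enriched_pairs Tibble with columns `res1`, `res2`, `k`, `rate`
#'   (see [default_enriched_pairs()]), or NULL for no planted signal.
#' @param seed Integer seed.
#' @return A labeled sequence tibble (`id`, `residues`, `length`, `label`)
#'   with attributes `ground_truth` (tibble of planted descriptors) and
#'   `config` (the full generator configuration).
#' @export
#' @examples
#' d <- simulate_enzyme_dataset(n_pos = 5, n_neg = 5, seed = 1)
#' attr(d, "ground_truth")
simulate_enzyme_dataset <- function(n_pos = 100, n_neg = 100,
                                    length_range = c(100L, 400L),
                                    background = rep(1 / 20, 20),
                                    enriched_pairs = default_enriched_pairs(),
                                    seed = 1) {
  .check_generator_config(n_pos, n_neg, length_range, background,
                          enriched_pairs)
  rng <- .new_rng(seed)
  n <- n_pos + n_neg
  lengths <- length_range[1] +
    .with_rng(rng, sample.int(length_range[2] - length_range[1] + 1L, n,
                              replace = TRUE)) - 1L
  labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
  residues <- character(n)
  for (i in seq_len(n)) {
    pairs <- if (labels[i] == "positive") enriched_pairs else NULL
    residues[i] <- .generate_sequence(lengths[i], background, pairs, rng)
  }
  truth <- if (is.null(enriched_pairs) || nrow(enriched_pairs) == 0) {
    tibble::tibble(descriptor = character(), res1 = character(),
                   res2 = character(), k = integer(), rate = numeric())
  } else {
    dplyr::mutate(
      enriched_pairs,
      descriptor = paste0(res1, strrep("*", k), res2), .before = 1)
  }
  out <- tibble::tibble(
    id = sprintf("%s_%03d", ifelse(labels == "positive", "enz", "non"),
                 stats::ave(seq_len(n), labels, FUN = seq_along)),
    residues = residues,
    length = lengths,
    label = factor(labels, levels = c("positive", "negative"))
  )
  attr(out, "ground_truth") <- truth
  attr(out, "config") <- list(
    n_pos = n_pos, n_neg = n_neg, length_range = as.integer(length_range),
    background = background,
    enriched_pairs = if (is.null(enriched_pairs)) NULL else as.list(enriched_pairs),
    seed = seed)
  out
}

.check_generator_config <- function(n_pos, n_neg, length_range, background,
                                    enriched_pairs) {
  stopifnot(n_pos >= 1, n_neg >= 1,
            length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2],
            length(background) == 20)
  if (abs(sum(background) - 1) > 1e-8) {
    stop("background probabilities must sum to 1 (got ",
         format(sum(background)), ")", call. = FALSE)
  }
  if (!is.null(enriched_pairs) && nrow(enriched_pairs) > 0) {
    stopifnot(all(c("res1", "res2", "k", "rate") %in% names(enriched_pairs)),
              all(enriched_pairs$res1 %in% amino_acids()),
              all(enriched_pairs$res2 %in% amino_acids()),
              all(enriched_pairs$k >= 0),
              all(enriched_pairs$rate >= 0 & enriched_pairs$rate <= 1))
    if (length_range[1] < max(enriched_pairs$k) + 2) {
      stop("minimum length must be >= max(k) + 2 = ",
           max(enriched_pairs$k) + 2, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# One sequence: background draw, then per-pair per-position overwrite.
.generate_sequence <- function(length, background, enriched_pairs, rng) {
  aa <- amino_acids()
  idx <- .with_rng(rng, sample.int(20L, length, replace = TRUE,
                                   prob = background))
  ch <- aa[idx]
  if (!is.null(enriched_pairs) && nrow(enriched_pairs) > 0) {
    for (r in seq_len(nrow(enriched_pairs))) {
      k <- enriched_pairs$k[r]
      rate <- enriched_pairs$rate[r]
      n_pos <- length - k - 1L
      if (n_pos < 1) next
      hit <- .rng_runif(rng, n_pos) < rate
      for (p in which(hit)) {
        ch[p] <- enriched_pairs$res1[r]
        ch[p + k + 1L] <- enriched_pairs$res2[r]
      }
    }
  }
  paste(ch, collapse = "")
}

#' Write a simulated dataset to FASTA + labels + ground-truth manifest
#'
#' Emits `sequences.fasta`, `labels.tsv` (columns id, label in {1, 0}) and
#' `ground_truth.json` (planted pairs and generator configuration) into
#' `dir`, the on-disk interchange format the command-line interface
#' consumes.
#'
#' @param dataset Tibble from [simulate_enzyme_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_fasta(dataset, paths["fasta"])
  readr::write_tsv(
    tibble::tibble(id = dataset$id,
                   label = as.integer(dataset$label == "positive")),
    paths["labels"])
  jsonlite::write_json(
    list(ground_truth = attr(dataset, "ground_truth"),
         config = attr(dataset, "config")),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
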