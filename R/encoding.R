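#' Amino acid composition (AAC) of protein sequences
#'
#' Computes the 20-component AAC vector for each sequence: component i is
#' N(i)/L, the count of amino acid i divided by the sequence length, so the
#' components sum to 1. Columns follow the alphabetical one-letter order
#' given by [amino_acids()].
#'
#' @param sequences A tibble with `id` and `residues` columns (and
#'   optionally `label`), or a character vector of sequences.
#' @return A tibble with `id` (and `label` if present) followed by 20
#'   frequency columns named by residue.
#' @export
#' @examples
#' encode_aac(tibble::tibble(id = "s1", residues = "ACDE"))
encode_aac <- function(sequences) {
  sequences <- .as_sequence_tbl(sequences)
  .assert_encodable(sequences, k = NULL)
  aa <- amino_acids()
  mat <- t(vapply(sequences$residues, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    tabulate(match(ch, aa), nbins = 20L) / length(ch)
  }, numeric(20), USE.NAMES = FALSE))
  colnames(mat) <- aa
  .bind_feature_cols(sequences, mat)
}

#' Composition of k-spaced amino acid pairs (CKSAAP)
#'
#' Computes the 400-component CKSAAP vector at gap `k` for each sequence.
#' N(i, j) counts ordered pairs of residues at positions (p, p + k + 1),
#' i.e. with exactly k residues strictly between them, over
#' p = 1 ... L - k - 1. Two denominator conventions are supported:
#'
#' * `"paper"` (default): f(i, j) = N(i, j) / (L - k), the formula as
#'   printed in the original description of the descriptor. Components then
#'   sum to (L - k - 1)/(L - k), slightly below 1.
#' * `"pair-count"`: f(i, j) = N(i, j) / (L - k - 1), dividing by the actual
#'   number of k-spaced pairs so components sum to exactly 1.
#'
#' The dipeptide composition (DPC) is the k = 0 case.
#'
#' @inheritParams encode_aac
#' @param k Gap size, a non-negative integer. Every sequence must satisfy
#'   L >= k + 2 (at least one k-spaced pair).
#' @param convention Denominator convention, `"paper"` or `"pair-count"`.
#' @return A tibble with `id` (and `label` if present) followed by 400
#'   frequency columns named per [cksaap_descriptors()].
#' @export
#' @examples
#' encode_cksaap(tibble::tibble(id = "s1", residues = "ACACA"), k = 1)
encode_cksaap <- function(sequences, k,
                          convention = c("paper", "pair-count")) {
  convention <- match.arg(convention)
  sequences <- .as_sequence_tbl(sequences)
  .assert_encodable(sequences, k = k)
  aa <- amino_acids()
  mat <- t(vapply(sequences$residues, function(s) {
    idx <- match(strsplit(s, "", fixed = TRUE)[[1]], aa)
    L <- length(idx)
    n_pairs <- L - k - 1L
    code <- (idx[seq_len(n_pairs)] - 1L) * 20L + idx[seq_len(n_pairs) + k + 1L]
    counts <- tabulate(code, nbins = 400L)
    denom <- if (convention == "paper") L - k else n_pairs
    counts / denom
  }, numeric(400), USE.NAMES = FALSE))
  colnames(mat) <- cksaap_descriptors(k)
  .bind_feature_cols(sequences, mat)
}

#' Assemble a labeled feature matrix from sequences
#'
#' Encodes a sequence dataset into a single feature tibble: an optional AAC
#' block (alphabet order) followed by one CKSAAP block per gap value in `k`
#' (ascending, each in row-major pair order). A descriptor subset restricts
#' and orders the columns: AAC descriptors first in alphabet order, then the
#' subset's pairs in the order given.
#'
#' @inheritParams encode_cksaap
#' @param aac Include the 20 AAC components?
#' @param k Integer vector of CKSAAP gap sizes (possibly empty).
#' @param descriptors Optional character vector of descriptor names (AAC
#'   letters and/or CKSAAP pair names such as `"A***L"`) to keep. Gap sizes
#'   present in the subset are encoded even if absent from `k`. When the
#'   subset names no AAC letters and `aac = TRUE`, the full AAC block is
#'   kept alongside the listed pairs (the usual "AAC plus selected pairs"
#'   configuration).
#' @return A feature tibble: `id`, `label` (if present in the input), then
#'   one numeric column per descriptor, all values in [0, 1].
#' @export
#' @examples
#' d <- tibble::tibble(id = c("a", "b"), residues = c("ACDEFG", "LLLLLL"))
#' dim(encode_features(d, k = 0:5))
encode_features <- function(sequences, aac = TRUE, k = integer(),
                            convention = c("paper", "pair-count"),
                            descriptors = NULL) {
  convention <- match.arg(convention)
  sequences <- .as_sequence_tbl(sequences)
  k <- sort(unique(as.integer(k)))
  if (!is.null(descriptors)) {
    info <- parse_descriptors(descriptors)
    aac <- aac || any(info$kind == "AAC")
    k_sub <- sort(unique(info$k[info$kind == "CKSAAP"]))
    k <- sort(union(k, k_sub))
  }
  if (!aac && length(k) == 0) {
    stop("no features requested: AAC disabled and no CKSAAP gap sizes",
         call. = FALSE)
  }
  blocks <- list()
  if (aac) blocks <- c(blocks, list(encode_aac(sequences)))
  for (kk in k) {
    blocks <- c(blocks, list(encode_cksaap(sequences, kk, convention)))
  }
  meta_cols <- intersect(c("id", "label"), names(blocks[[1]]))
  feats <- lapply(blocks, function(b) b[, setdiff(names(b), meta_cols)])
  out <- dplyr::bind_cols(blocks[[1]][, meta_cols, drop = FALSE], feats)
  if (!is.null(descriptors)) {
    info <- parse_descriptors(descriptors)
    aac_keep <- if (any(info$kind == "AAC")) {
      sort(info$descriptor[info$kind == "AAC"])
    } else if (aac) amino_acids() else character()
    keep <- c(aac_keep, info$descriptor[info$kind == "CKSAAP"])
    out <- out[, c(meta_cols, keep)]
  }
  out
}

# Accept a plain character vector or a tibble of sequences.
.as_sequence_tbl <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(
      id = paste0("seq", seq_along(sequences)), residues = sequences)
  }
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  sequences
}

.assert_encodable <- function(sequences, k = NULL) {
  L <- nchar(sequences$residues)
  if (any(L < 1)) {
    stop("empty sequence: ", sequences$id[which(L < 1)[1]], call. = FALSE)
  }
  ch <- unique(unlist(strsplit(sequences$residues, "", fixed = TRUE)))
  bad <- setdiff(ch, amino_acids())
  if (length(bad) > 0) {
    stop("non-standard residue(s) ", paste(bad, collapse = ", "),
         "; run validate_sequences() / load_labeled_dataset() first",
         call. = FALSE)
  }
  if (!is.null(k)) {
    stopifnot(length(k) == 1, k >= 0, k == as.integer(k))
    short <- L < k + 2
    if (any(short)) {
      i <- which(short)[1]
      stop("sequence '", sequences$id[i], "' (L = ", L[i],
           ") is too short for gap k = ", k, " (need L >= k + 2)",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

.bind_feature_cols <- function(sequences, mat) {
  meta <- sequences[, intersect(c("id", "label"), names(sequences)),
                    drop = FALSE]
  dplyr::bind_cols(tibble::as_tibble(meta), tibble::as_tibble(mat))
}

#' Feature columns of a feature tibble
#'
#' @param features A feature tibble from [encode_features()].
#' @return Character vector of descriptor column names (everything except
#'   `id` and `label`).
#' @export
feature_names <- function(features) {
  setdiff(names(features), c("id", "label"))
}

#' Write / read a feature matrix as TSV with a JSON encoding sidecar
#'
#' The TSV has `id` (and `label` when present) first, then one named column
#' per descriptor. A JSON sidecar (`<path>.json`) records the encoding
#' specification (gap list, denominator convention, column order) so the
#' matrix reloads bit-exactly and new sequences can be encoded identically.
#'
#' @param features Feature tibble from [encode_features()].
#' @param path Output TSV path.
#' @param spec Optional encoding spec list (as built by [encoding_spec()]).
#' @param digits Decimal places written to the TSV.
#' @return `path`, invisibly (write) / the feature tibble (read).
#' @export
write_features <- function(features, path, spec = NULL, digits = 6) {
  out <- features
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, digits))
  readr::write_tsv(out, path)
  sidecar <- list(columns = names(features), digits = digits)
  if (!is.null(spec)) sidecar$spec <- unclass(spec)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    tbl <- tbl[, meta$columns]
  }
  if ("label" %in% names(tbl)) {
    tbl$label <- factor(tbl$label, levels = c("positive", "negative"))
  }
  tbl
}

#' Build an encoding specification
#'
#' A small list describing how sequences are turned into features; embedded
#' in saved models and feature-matrix sidecars so encodings are reproducible.
#'
#' @inheritParams encode_features
#' @return A list with class `"enzid_encoding_spec"`.
#' @export
encoding_spec <- function(aac = TRUE, k = integer(),
                          convention = c("paper", "pair-count"),
                          descriptors = NULL) {
  convention <- match.arg(convention)
  structure(list(aac = aac, k = as.integer(k), convention = convention,
                 descriptors = descriptors),
            class = "enzid_encoding_spec")
}

# Apply a stored encoding spec to new sequences.
.encode_with_spec <- function(sequences, spec) {
  encode_features(sequences, aac = spec$aac, k = spec$k,
                  convention = spec$convention,
                  descriptors = spec$descriptors)
}
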