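#' The 20 standard amino acids
#'
#' One-letter codes of the 20 standard amino acids in alphabetical order.
#' This ordering fixes the index-to-residue mapping used by every encoder
#' in the package: AAC component i is the frequency of `amino_acids()[i]`,
#' and CKSAAP pair (i, j) refers to the same indices.
#'
#' @return A character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Residues excluded as ambiguous during dataset curation.
AMBIGUOUS_RESIDUES <- c("B", "J", "O", "U", "X", "Z")

#' Canonical CKSAAP descriptor names for a gap size
#'
#' Descriptor names for the 400 ordered k-spaced amino-acid pairs, in
#' row-major order over the alphabet (AA, AC, ..., AY, CA, ..., YY). A pair
#' with gap `k` is displayed with `k` stars between its members, e.g.
#' `"A***L"` for (A, L) with three intervening residues.
#'
#' @param k Gap size (number of residues strictly between the pair members),
#'   a non-negative integer.
#' @return Character vector of 400 descriptor names.
#' @export
#' @examples
#' head(cksaap_descriptors(3))
cksaap_descriptors <- function(k) {
  stopifnot(length(k) == 1, k >= 0, k == as.integer(k))
  aa <- amino_acids()
  gap <- strrep("*", k)
  as.vector(t(outer(aa, aa, function(i, j) paste0(i, gap, j))))
}

#' Parse a CKSAAP descriptor name
#'
#' Inverse of [cksaap_descriptors()] naming: splits `"A***L"` into its first
#' residue, second residue and gap size. Plain single letters are AAC
#' descriptors.
#'
#' @param x Character vector of descriptor names.
#' @return A tibble with columns `descriptor`, `kind` ("AAC" or "CKSAAP"),
#'   `res1`, `res2` (NA for AAC) and `k` (NA for AAC).
#' @export
parse_descriptors <- function(x) {
  stopifnot(is.character(x))
  ok_aac <- x %in% amino_acids()
  m <- regmatches(x, regexec("^([A-Y])(\\**)([A-Y])$", x))
  ok_pair <- vapply(m, length, integer(1)) == 4L
  bad <- !(ok_aac | ok_pair)
  if (any(bad)) {
    stop("unrecognized descriptor name(s): ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    descriptor = x,
    kind = ifelse(ok_aac, "AAC", "CKSAAP"),
    res1 = ifelse(ok_aac, x, vapply(m, function(z) if (length(z) == 4) z[2] else NA_character_, character(1))),
    res2 = ifelse(ok_aac, NA_character_, vapply(m, function(z) if (length(z) == 4) z[4] else NA_character_, character(1))),
    k = ifelse(ok_aac, NA_integer_, vapply(m, function(z) if (length(z) == 4) nchar(z[3]) else NA_integer_, integer(1)))
  )
}

#' Informative 3-spaced amino-acid pairs for human-enzyme identification
#'
#' The reference set of 20 informative 3-spaced amino-acid pairs for the
#' human enzyme versus non-enzyme classification task, selected by ANOVA
#' F-score ranking with incremental forward selection on a curated UniProt
#' training set. Together with the 20 AAC components these form the 40-feature
#' configuration of the final published model. Provided so that configuration
#' can be reproduced on new data without re-running selection.
#'
#' @return Character vector of 20 CKSAAP (k = 3) descriptor names.
#' @export
#' @examples
#' informative_pairs_k3()
informative_pairs_k3 <- function() {
  c("L***L", "P***P", "A***A", "S***S", "G***G", "E***E", "K***K",
    "R***R", "A***L", "Q***Q", "E***K", "L***A", "K***E", "A***G",
    "L***G", "G***P", "S***L", "E***L", "V***L", "G***L")
}
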